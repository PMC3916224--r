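## Macromolecular coordinate I/O and tubulin heterodimer annotation.
##
## A structure_model is a thin, format-neutral atom table; parsing and
## serialisation of PDB/mmCIF go through bio3d.  Annotation attaches the
## tubulin domain decomposition (N-terminal nucleotide-binding, intermediate,
## C-terminal domains and the central H7 helix) to an alpha/beta chain pair.

#' Default tubulin domain decomposition
#'
#' Residue intervals (author numbering, inclusive on both ends) for the
#' canonical tubulin subunit: N-terminal nucleotide-binding domain 1-205,
#' intermediate domain 206-381, C-terminal domain 382-437, H7 helix 222-244.
#' The H7 interval may be overridden per subunit; a known alternate for
#' straight-control comparisons is alpha-H7 224-242 with beta-H7 224-243.
#'
#' @param n_terminal,intermediate,c_terminal length-2 integer vectors.
#' @param h7_alpha,h7_beta H7 helix intervals for each subunit.
#' @return list of residue intervals, class `domain_config`.
#' @examples
#' domain_config()
#' domain_config(h7_alpha = c(224, 242), h7_beta = c(224, 243))
#' @export
domain_config <- function(n_terminal = c(1L, 205L),
                          intermediate = c(206L, 381L),
                          c_terminal = c(382L, 437L),
                          h7_alpha = c(222L, 244L),
                          h7_beta = c(222L, 244L)) {
  iv <- list(n_terminal = n_terminal, intermediate = intermediate,
             c_terminal = c_terminal, h7_alpha = h7_alpha, h7_beta = h7_beta)
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2L || !is.numeric(v) || v[1L] > v[2L])
      stop("interval '", nm, "' must be (start, end) with start <= end")
    iv[[nm]] <- as.integer(v)
  }
  core <- rbind(iv$n_terminal, iv$intermediate, iv$c_terminal)
  if (any(core[-1L, 1L] <= core[-3L, 2L]))
    stop("n_terminal, intermediate and c_terminal intervals must be ",
         "ordered and non-overlapping")
  structure(iv, class = "domain_config")
}

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF coordinate file into a `structure_model`: an ordered
#' atom table (ATOM and HETATM records) with chains, author residue
#' numbering, insertion codes and coordinates preserved.  Alternate
#' locations are resolved to the highest-occupancy conformer (ties broken by
#' alphabetical altloc, so 'A' wins), which makes the selection
#' deterministic.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return a `structure_model`: list with `atoms` (data.frame: `type`,
#'   `elety`, `elesy`, `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`,
#'   `o`, `b`, `alt`), `het` (the HETATM subset), and `metadata`.
#' @examples
#' \dontrun{m <- read_structure("1jff.pdb")}
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    switch(format,
           pdb = bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE,
                                 multi = FALSE),
           cif = suppressWarnings(
             bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in '", path, "'")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  keep <- .resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  atoms <- data.frame(type = at$type, elety = at$elety, elesy = at$elesy,
                      resid = at$resid, chain = at$chain, resno = at$resno,
                      insert = at$insert, x = at$x, y = at$y, z = at$z,
                      o = at$o, b = at$b, alt = at$alt,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in '", path, "'")
  new_structure_model(atoms, metadata = list(
    identifier = sub("\\.[^.]*$", "", basename(path)),
    source = path, format = format))
}

## index vector keeping one conformer per (chain, resno, insert, elety):
## the highest-occupancy one, alphabetically-first altloc on ties
.resolve_altloc <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  sort(ord[!duplicated(key[ord])])
}

#' @keywords internal
new_structure_model <- function(atoms, metadata = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  structure(list(atoms = atoms,
                 het = atoms[atoms$type == "HETATM", , drop = FALSE],
                 metadata = metadata),
            class = "structure_model")
}

#' Build a structure_model from an atom table
#'
#' Constructor used by the synthetic-structure generator and by tests.
#' Columns `elety`, `resid`, `chain`, `resno`, `x`, `y`, `z` are required;
#' `type`, `insert`, `o`, `b`, `alt`, `elesy` get defaults.
#'
#' @param atoms data.frame of atom records.
#' @param identifier character label stored in the metadata.
#' @return a `structure_model`.
#' @export
structure_model <- function(atoms, identifier = "model") {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$type)) atoms$type <- rep("ATOM", n)
  if (is.null(atoms$insert)) atoms$insert <- rep("", n)
  if (is.null(atoms$o)) atoms$o <- rep(1, n)
  if (is.null(atoms$b)) atoms$b <- rep(0, n)
  if (is.null(atoms$alt)) atoms$alt <- rep("", n)
  if (is.null(atoms$elesy)) atoms$elesy <- .guess_element(atoms$elety)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  new_structure_model(atoms[, c("type", "elety", "elesy", "resid", "chain",
                                "resno", "insert", "x", "y", "z", "o", "b",
                                "alt")],
                      metadata = list(identifier = identifier,
                                      source = NA_character_,
                                      format = "constructed"))
}

.guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", toupper(elety))
  two <- substr(e, 1, 2)
  ifelse(two %in% c("CL", "BR", "MG", "ZN", "FE", "NA", "MN", "SE"),
         substr(paste0(toupper(substr(two, 1, 1)),
                       tolower(substr(two, 2, 2))), 1, 2),
         substr(e, 1, 1))
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model '%s': %d atoms (%d HETATM), chains %s\n",
              x$metadata$identifier, nrow(a), nrow(x$het),
              paste(sort(unique(a$chain)), collapse = " ")))
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' Serialises a `structure_model` back to PDB format.  Coordinates are
#' written at the format's printed precision (0.001 angstrom), so
#' read-write-read round trips preserve the atom table to that precision.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   type = a$type,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Annotate a structure as a tubulin heterodimer
#'
#' Binds an alpha and a beta chain of a structure to the tubulin domain
#' decomposition, checking that every configured interval resolves to at
#' least one CA atom in its chain.  Residues missing from a configured
#' interval (unmodelled loops) are tolerated: the working selection is the
#' intersection with the residues present, and the selection sizes are
#' reported via `message()`.
#'
#' @param structure a `structure_model`.
#' @param chain_map list or named vector with entries `alpha` and `beta`
#'   giving chain identifiers.
#' @param domains a [domain_config()].
#' @param quiet suppress the selection-size report.
#' @return a `tubulin_dimer`: list with `structure`, `alpha`, `beta`,
#'   `domains`, `ligands`.
#' @examples
#' \dontrun{dim <- annotate_dimer(m, list(alpha = "A", beta = "B"))}
#' @export
annotate_dimer <- function(structure, chain_map, domains = domain_config(),
                           quiet = FALSE) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(domains, "domain_config"))
  cm <- as.list(chain_map)
  if (!all(c("alpha", "beta") %in% names(cm)))
    stop("chain_map must name 'alpha' and 'beta' chains")
  a <- structure$atoms
  prot <- a[a$type == "ATOM", , drop = FALSE]
  for (role in c("alpha", "beta")) {
    ch <- cm[[role]]
    if (!ch %in% prot$chain)
      stop("chain '", ch, "' (", role, ") not present in structure")
  }
  for (role in c("alpha", "beta")) {
    ch <- cm[[role]]
    for (dom in c("n_terminal", "intermediate", "c_terminal",
                  if (role == "alpha") "h7_alpha" else "h7_beta")) {
      iv <- domains[[dom]]
      sel <- prot$chain == ch & prot$elety == "CA" &
        prot$resno >= iv[1L] & prot$resno <= iv[2L]
      n_ca <- sum(sel)
      if (n_ca == 0L)
        stop(role, "-subunit interval ", dom, " (", iv[1L], "-", iv[2L],
             ") resolves to zero CA atoms in chain ", ch)
      span <- iv[2L] - iv[1L] + 1L
      if (!quiet) {
        gap <- span - length(unique(prot$resno[sel]))
        message(sprintf("%s %s %d-%d: %d CA atoms%s", role, dom,
                        iv[1L], iv[2L], n_ca,
                        if (gap > 0) sprintf(" (%d residues missing)", gap)
                        else ""))
      }
    }
  }
  structure(list(structure = structure, alpha = cm$alpha, beta = cm$beta,
                 domains = domains,
                 ligands = unique(structure$het$resid)),
            class = "tubulin_dimer")
}

#' @export
print.tubulin_dimer <- function(x, ...) {
  cat(sprintf("tubulin_dimer: alpha chain %s, beta chain %s\n",
              x$alpha, x$beta))
  cat(sprintf("  H7 alpha %d-%d, beta %d-%d; ligands: %s\n",
              x$domains$h7_alpha[1], x$domains$h7_alpha[2],
              x$domains$h7_beta[1], x$domains$h7_beta[2],
              if (length(x$ligands)) paste(x$ligands, collapse = " ")
              else "none"))
  invisible(x)
}

## Atom selection helpers -----------------------------------------------

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

## rows of the protein atom table for one subunit/domain/variant
#' Select atoms of a dimer subunit
#'
#' Returns the atom-table rows of one subunit restricted to a domain
#' interval and an atom-selection variant (`"all"` atoms, `"backbone"`
#' N-CA-C-O, or `"calpha"`).
#'
#' @param dimer a `tubulin_dimer`.
#' @param subunit `"alpha"` or `"beta"`.
#' @param domain one of `"n_terminal"`, `"intermediate"`, `"c_terminal"`,
#'   `"h7"`, or `"all"` for the whole chain.
#' @param variant atom-selection variant.
#' @return data.frame of atom records.
#' @export
select_atoms <- function(dimer, subunit = c("alpha", "beta"),
                         domain = c("all", "n_terminal", "intermediate",
                                    "c_terminal", "h7"),
                         variant = c("all", "backbone", "calpha")) {
  subunit <- match.arg(subunit)
  domain <- match.arg(domain)
  variant <- match.arg(variant)
  a <- dimer$structure$atoms
  a <- a[a$type == "ATOM" & a$chain == dimer[[subunit]], , drop = FALSE]
  if (domain != "all") {
    key <- if (domain == "h7") paste0("h7_", subunit) else domain
    iv <- dimer$domains[[key]]
    a <- a[a$resno >= iv[1L] & a$resno <= iv[2L], , drop = FALSE]
  }
  switch(variant,
         all = a,
         backbone = a[a$elety %in% BACKBONE_ATOMS, , drop = FALSE],
         calpha = a[a$elety == "CA", , drop = FALSE])
}

## pair two atom tables across structures on (resno, insert, elety);
## returns list of equal-length coordinate matrices
.pair_atoms <- function(a, b) {
  ka <- paste(a$resno, a$insert, a$elety, sep = "\r")
  kb <- paste(b$resno, b$insert, b$elety, sep = "\r")
  common <- intersect(ka, kb)
  ia <- match(common, ka)
  ib <- match(common, kb)
  list(a = as.matrix(a[ia, c("x", "y", "z")]),
       b = as.matrix(b[ib, c("x", "y", "z")]),
       n = length(common))
}
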