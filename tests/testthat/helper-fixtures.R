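# Fixture builders and independent oracles shared across the test files.
# All fixtures are generated in code; oracles are deliberately naive
# (brute force, closed form, quadrature) and independent of the package's
# own algorithms.

pdb_line <- function(serial, name, resid, chain, resno, x, y, z, occ = 1,
                     alt = "", type = "ATOM", elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, alt, resid, chain, resno, x, y, z, occ, 0, elesy)
}

# hand-written 3-residue, 1-chain PDB with an altloc pair and a GDP HETATM
write_tiny_pdb <- function(path) {
  writeLines(c(
    pdb_line(1, "N",  "ALA", "A", 1, 0.000, 0.000, 0.000),
    pdb_line(2, "CA", "ALA", "A", 1, 1.458, 0.000, 0.000),
    pdb_line(3, "C",  "ALA", "A", 1, 2.100, 1.300, 0.000),
    pdb_line(4, "CA", "GLY", "A", 2, 4.000, 1.500, 0.500, occ = 0.4,
             alt = "A"),
    pdb_line(5, "CA", "GLY", "A", 2, 4.200, 1.600, 0.600, occ = 0.6,
             alt = "B"),
    pdb_line(6, "CA", "SER", "A", 3, 7.000, 2.000, 1.000),
    pdb_line(7, "PB", "GDP", "A", 90, 9.000, 9.000, 9.000,
             type = "HETATM", elesy = "P"),
    "END"), path)
  path
}

write_tiny_cif <- function(path) {
  writeLines(c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.100 1.300 0.000 1.00 0.00 ? 1 ALA A C 1",
    "#"), path)
  path
}

# full-length two-chain CA-only tubulin stand-in covering residues 1-437,
# for annotation bookkeeping tests
make_ca_dimer_model <- function(missing = integer()) {
  resno <- setdiff(1:437, missing)
  one <- function(chain, y0) {
    data.frame(elety = "CA", resid = "GLY", chain = chain, resno = resno,
               x = resno * 1.1, y = y0 + sin(resno), z = cos(resno))
  }
  structure_model(rbind(one("A", 0), one("B", 40)), "ca_dimer")
}

# O(n^2) brute-force clash enumeration
bf_clashes <- function(xa, ea, xb, eb, scale = 0.75, same = FALSE) {
  ra <- vdw_radii(ea); rb <- vdw_radii(eb)
  out <- list()
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    if (same && j <= i) next
    d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    if (d < scale * (ra[i] + rb[j]))
      out[[length(out) + 1L]] <- c(i, j, d)
  }
  if (!length(out)) return(matrix(numeric(), 0, 3))
  do.call(rbind, out)
}

# closed-form SASA of two intersecting spheres (spherical caps)
cap_sasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# brute-force rotation-grid RMSD minimisation (coarse scan + refinement)
grid_min_rmsd <- function(mob, ref, coarse = 15, fine = 1) {
  mc <- sweep(mob, 2, colMeans(mob)); rc <- sweep(ref, 2, colMeans(ref))
  eval_at <- function(ang) {
    r <- rotation_about_axis(c(0, 0, 1), ang[3]) %*%
      rotation_about_axis(c(0, 1, 0), ang[2]) %*%
      rotation_about_axis(c(1, 0, 0), ang[1])
    sqrt(mean(rowSums((mc %*% r - rc)^2)))
  }
  scan <- function(center, span, step) {
    best <- Inf; bang <- center
    for (ax in seq(center[1] - span, center[1] + span, by = step))
      for (ay in seq(center[2] - span, center[2] + span, by = step))
        for (az in seq(center[3] - span, center[3] + span, by = step)) {
          v <- eval_at(c(ax, ay, az))
          if (v < best) { best <- v; bang <- c(ax, ay, az) }
        }
    list(rmsd = best, ang = bang)
  }
  g <- scan(c(0, 0, 0), 180, coarse)
  scan(g$ang, coarse, fine)$rmsd
}

# brute-force normal-grid plane residual
grid_min_plane_resid <- function(pts, n_dirs = 20000) {
  cen <- sweep(pts, 2, colMeans(pts))
  dirs <- bendscape:::.sphere_points(n_dirs)
  min(apply(dirs, 1, function(n) sqrt(mean((cen %*% n)^2))))
}

# combined-H7 plane normal of the straight synthetic dimer (for the
# closed-form rotated-normal oracle)
h7_plane_normal <- function(dimer, variant = "all") {
  xyz <- rbind(
    as.matrix(select_atoms(dimer, "alpha", "h7", variant)[, c("x", "y", "z")]),
    as.matrix(select_atoms(dimer, "beta", "h7", variant)[, c("x", "y", "z")]))
  fit_plane(xyz)$normal
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
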