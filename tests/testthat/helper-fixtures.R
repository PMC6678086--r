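# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

# A minimal topology: one chain of n CA pseudo-residues.
make_ca_topology <- function(n, chain = "A") {
  domainmotion:::new_topology(data.frame(
    chain_id = chain, resnum = seq_len(n), inscode = " ",
    resname = "ALA", atom_name = "CA", element = "C",
    stringsAsFactors = FALSE))
}

make_test_trajectory <- function(coords_list, topology = NULL,
                                 dt_ns = 0.04) {
  na <- nrow(coords_list[[1]])
  if (is.null(topology)) topology <- make_ca_topology(na)
  coords <- array(unlist(coords_list), dim = c(na, 3L, length(coords_list)))
  domainmotion:::new_trajectory(topology, coords,
                                seq_along(coords_list) * dt_ns)
}

# Uniformly random proper rotation matrix (QR of Gaussian + sign fix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Anisotropic cloud with distinct principal SDs (PCA-identifiable).
anisotropic_cloud <- function(n, sds = c(0.9, 0.6, 0.3)) {
  matrix(rnorm(n * 3), n, 3) %*% diag(sds)
}

# Center a cloud and rotate it onto its own principal axes, then rescale
# the columns so the sample covariance is EXACTLY diag(sds^2): used to
# construct clouds with controlled (near-)degenerate eigenvalue gaps.
exact_cov_cloud <- function(n, sds) {
  cloud <- anisotropic_cloud(n, sds)
  lf <- pca_frame(cloud)
  canon <- sweep(cloud, 2, lf$origin) %*% lf$axes
  for (j in 1:3) canon[, j] <- canon[, j] * sds[j] /
      sqrt(mean(canon[, j]^2))
  canon
}

# Independent brute-force RMSD oracle: its own centering + SVD fit and an
# explicit per-atom deviation sum, no shared code with rmsd_series().
brute_rmsd <- function(dom, ref_dom) {
  mc <- colMeans(dom); rc <- colMeans(ref_dom)
  X <- sweep(dom, 2, mc); Y <- sweep(ref_dom, 2, rc)
  s <- svd(t(X) %*% Y)
  d <- sign(det(s$v %*% t(s$u))); if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(X %*% t(R), 2, rc, `+`)
  acc <- 0
  for (i in seq_len(nrow(moved)))
    acc <- acc + sum((moved[i, ] - ref_dom[i, ])^2)
  sqrt(acc / nrow(moved))
}

# Write a tiny PDB file from records given as a data frame with columns
# chain, resnum, resname, atom, x, y, z (Angstrom), and optional altloc /
# occupancy, returning the path.
write_test_pdb <- function(df, path = tempfile(fileext = ".pdb"),
                           model_blocks = NULL) {
  fmt <- function(i, serial) {
    altloc <- if (!is.null(df$altloc)) df$altloc[i] else " "
    occ <- if (!is.null(df$occupancy)) df$occupancy[i] else 1.0
    sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
            serial, df$atom[i], altloc, df$resname[i], df$chain[i],
            df$resnum[i], df$x[i], df$y[i], df$z[i], occ, 0.0,
            substr(df$atom[i], 1, 1))
  }
  lines <- character(0)
  if (is.null(model_blocks)) {
    lines <- vapply(seq_len(nrow(df)), function(i) fmt(i, i), character(1))
  } else {
    for (m in seq_len(model_blocks)) {
      lines <- c(lines, sprintf("MODEL     %4d", m),
                 vapply(seq_len(nrow(df)), function(i) fmt(i, i),
                        character(1)),
                 "ENDMDL")
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# 9-residue peptide chain C (synthetic stand-in for a class I MHC groove
# peptide with sequence EEYLQAFTY); CA only, arbitrary coordinates.
synthetic_peptide_pdb <- function(path = tempfile(fileext = ".pdb")) {
  seq3 <- c("GLU", "GLU", "TYR", "LEU", "GLN", "ALA", "PHE", "THR", "TYR")
  df <- data.frame(chain = "C", resnum = seq_along(seq3), resname = seq3,
                   atom = "CA", x = seq_along(seq3) * 3.8, y = 0, z = 0)
  write_test_pdb(df, path)
}
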