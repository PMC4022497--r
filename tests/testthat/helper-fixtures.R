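# Fixtures are built in code: hand-formatted PDB records, directly
# constructed interface objects, and random rigid-body transforms.

pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     alt = " ", icode = " ", occ = 1.00, b = 0.00,
                     type = "ATOM", elem = substr(trimws(name), 1L, 1L)) {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, alt, resn, chain, resno, icode,
          x, y, z, occ, b, elem)
}

# One full residue (N, CA, C, O) centred on a CA position.
residue_lines <- function(serial0, resn, chain, resno, ca, icode = " ",
                          drop = character(0)) {
  offs <- list(N = c(-0.8, 0.6, 0), CA = c(0, 0, 0),
               C = c(0.8, 0.6, 0), O = c(1.4, -0.2, 0))
  offs <- offs[setdiff(names(offs), drop)]
  mapply(function(nm, k) {
    pdb_line(serial0 + k, nm, resn, chain, resno,
             ca[1] + offs[[nm]][1], ca[2] + offs[[nm]][2], ca[3] + offs[[nm]][3],
             icode = icode)
  }, names(offs), seq_along(offs) - 1L)
}

write_pdb_fixture <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

# Two chains of three residues each; closest heavy-atom contact is set by
# `gap` (x-separation of the CA columns).
two_chain_pdb <- function(gap = 3.5, file = tempfile(fileext = ".pdb")) {
  lines <- character(0)
  s <- 1L
  for (i in 1:3) {
    lines <- c(lines, residue_lines(s, "ALA", "A", i, c(0, 4 * (i - 1), 0)))
    s <- s + 4L
  }
  for (i in 1:3) {
    lines <- c(lines, residue_lines(s, "LEU", "B", i, c(gap, 4 * (i - 1), 0)))
    s <- s + 4L
  }
  write_pdb_fixture(lines, file)
}

# Interface object built directly (bypassing the PDB layer) for geometry
# and feature tests.
make_interface <- function(xyz, ddg = NULL, resname = "ALA",
                           chain = NULL, id = "test_AB") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  chain <- chain %||% rep(c("A", "B"), length.out = n)
  resname <- rep(resname, length.out = n)
  ddg <- if (is.null(ddg)) rep(NA_real_, n) else ddg
  structure(list(id = id, pdb_id = "test", chain_a = "A", chain_b = "B",
                 cutoff = Inf,
                 residues = data.frame(chain = chain,
                                       resseq = seq_len(n), icode = rep("", n),
                                       resname = resname,
                                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                       backbone_complete = rep(TRUE, n),
                                       nonstandard = rep(FALSE, n),
                                       ddg = ddg,
                                       stringsAsFactors = FALSE),
                 category = "unknown", subcategory = "unknown",
                 het_near = FALSE, het_near_names = character(0)),
            class = "ecr_interface")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical feature order (mirrors the package's exported column contract)
ECR_FEATURES <- c("slope_ddg", "intcpt_ddg", "r2_ddg", "sum_ddg",
                  "avg_ddg", "n_total", "n_hot", "frac_hot")

# Uniformly random rotation matrix (QR of a Gaussian matrix, det fixed to +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_interface <- function(interface, rot = random_rotation(),
                                shift = stats::rnorm(3, sd = 20)) {
  xyz <- as.matrix(interface$residues[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rot), 2L, shift, "+")
  interface$residues$x <- xyz[, 1]
  interface$residues$y <- xyz[, 2]
  interface$residues$z <- xyz[, 3]
  interface
}

# Closed-form two-variable OLS (normal equations) -- the independent oracle
# for the energy-centrality regression.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r2 = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}

# Exhaustive-enumeration k = 2 clustering oracle: global minimum
# within-cluster sum of squares over all 2-partitions.
kmeans2_bruteforce <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- Inf
  best_asg <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {
    asg <- c(1L, as.integer(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0) + 1L)
    if (length(unique(asg)) < 2L) next
    ss <- 0
    for (k in 1:2) {
      pts <- x[asg == k, , drop = FALSE]
      ss <- ss + sum(sweep(pts, 2L, colMeans(pts))^2)
    }
    if (ss < best) { best <- ss; best_asg <- asg }
  }
  list(inertia = best, assignments = best_asg)
}

same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}
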