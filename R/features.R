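# The energy centrality relationship (ECR) features: centre of interface,
# per-residue radial displacement, the ddG-vs-distance regression, and the
# eight per-interface scalars fed to the classifier.

#' Centre of interface and radial displacements
#'
#' The centre of interface (CoI) is the unweighted arithmetic mean of the
#' C-alpha positions of *all* interfacial residues (including those with a
#' missing ddG).  Each residue's displacement `dr` is the Euclidean distance
#' of its C-alpha from the CoI, in angstroms.
#'
#' @param interface An `ecr_interface` with at least one residue.
#' @return A list of class `ecr_geometry` with `coi` (length-3 numeric) and
#'   `dr` (one non-negative distance per residue, in residue order).
#' @export
center_of_interface <- function(interface) {
  stopifnot(inherits(interface, "ecr_interface"))
  res <- interface$residues
  if (nrow(res) == 0L) stop_degenerate("interface has no residues")
  xyz <- as.matrix(res[, c("x", "y", "z")])
  coi <- colMeans(xyz)
  dr <- sqrt(rowSums(sweep(xyz, 2L, coi)^2))
  structure(list(coi = coi, dr = unname(dr)), class = "ecr_geometry")
}

#' Energy-centrality regression of an interface
#'
#' Fits the first-order model `ddG = slope * dr + intercept` by ordinary
#' least squares over the residues with a ddG value, where `dr` is the
#' distance of each residue from the centre of interface.  A FLIP-like
#' interface typically shows a positive intercept (hot centre) and a
#' negative slope (energetic importance decaying outwards).
#'
#' @param interface An `ecr_interface` whose residues carry ddG values.
#' @param geometry Optional precomputed [center_of_interface()] result.
#' @return A list with `slope` (kcal/mol/A), `intercept` (kcal/mol) and `r2`
#'   (coefficient of determination; defined as 0 when the response has zero
#'   variance).
#' @export
fit_energy_centrality <- function(interface, geometry = center_of_interface(interface)) {
  stopifnot(inherits(interface, "ecr_interface"))
  ddg <- interface$residues$ddg
  ok <- is.finite(ddg)
  if (sum(ok) < 3L) {
    stop_degenerate("energy-centrality regression needs at least 3 residues with ddG (got ",
                    sum(ok), ")")
  }
  x <- geometry$dr[ok]
  y <- ddg[ok]
  if (diff(range(x)) == 0) {
    stop_degenerate("all residues equidistant from the centre of interface; slope undefined")
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # r2 from the residuals directly; zero response variance is defined as 0
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(co[2L]), intercept = unname(co[1L]), r2 = r2)
}

#' Compute the eight ECR features of one interface
#'
#' The features are: `slope_ddg`, `intcpt_ddg` and `r2_ddg` from the
#' energy-centrality regression; `sum_ddg` (net sum of ddG over scanned
#' residues, kcal/mol); `avg_ddg` (mean ddG over scanned residues);
#' `n_total` (total interfacial residue count -- by default including
#' residues without a ddG value, see `total_counts_all`); `n_hot` (residues
#' with ddG strictly greater than `hot_threshold`); and
#' `frac_hot = n_hot / n_total`.
#'
#' @param interface An `ecr_interface` with ddG attached.
#' @param hot_threshold Hotspot threshold in kcal/mol (default +1.0; the
#'   comparison is strict, so a residue at exactly the threshold is not hot).
#' @param total_counts_all If `TRUE` (default) `n_total` counts every
#'   interfacial residue, including Gly/Pro and residues with no matching
#'   ddG; if `FALSE` it counts only scanned residues.
#' @return A one-row data frame: `id`, `category`, `subcategory`, then the
#'   eight features in canonical order.
#' @export
compute_features <- function(interface, hot_threshold = 1.0, total_counts_all = TRUE) {
  stopifnot(inherits(interface, "ecr_interface"))
  geom <- center_of_interface(interface)
  fit <- fit_energy_centrality(interface, geom)
  ddg <- interface$residues$ddg
  ok <- is.finite(ddg)
  sum_ddg <- sum(ddg[ok])
  avg_ddg <- sum_ddg / sum(ok)
  n_total <- if (total_counts_all) nrow(interface$residues) else sum(ok)
  n_hot <- sum(ddg[ok] > hot_threshold)
  data.frame(id = interface$id,
             category = interface$category,
             subcategory = interface$subcategory,
             slope_ddg = fit$slope,
             intcpt_ddg = fit$intercept,
             r2_ddg = fit$r2,
             sum_ddg = sum_ddg,
             avg_ddg = avg_ddg,
             n_total = n_total,
             n_hot = n_hot,
             frac_hot = n_hot / n_total,
             stringsAsFactors = FALSE)
}

#' Feature table for a set of interfaces
#'
#' @param interfaces A list of `ecr_interface` objects (or of synthetic
#'   interfaces from the generator, whose `$interface` element is used).
#' @param ... Passed on to [compute_features()].
#' @return A data frame with one row per interface.
#' @export
ecr_feature_table <- function(interfaces, ...) {
  rows <- lapply(interfaces, function(x) {
    if (inherits(x, "ecr_synth")) x <- x$interface
    compute_features(x, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-dimensional plotting projection of an interface
#'
#' Projects the interfacial C-alpha coordinates onto the first two principal
#' axes of their own scatter (so the interface lies "face on" in the plot
#' plane), and normalizes ddG by the maximum absolute ddG so values fall in
#' \[-1, 1\].  Distances from the centre of interface are reported both raw
#' and normalized by the maximum distance.
#'
#' @param interface An `ecr_interface` with at least 3 residues.
#' @return A data frame with one row per residue: `chain`, `resseq`,
#'   `icode`, `pc1`, `pc2`, `dr`, `dr_norm`, `ddg`, `ddg_norm`.  The
#'   attribute `"axis2_defined"` is `FALSE` when the geometry is collinear
#'   and the second axis is arbitrary.
#' @export
plot_projection <- function(interface) {
  stopifnot(inherits(interface, "ecr_interface"))
  res <- interface$residues
  if (nrow(res) < 3L) stop_degenerate("projection needs at least 3 residues")
  xyz <- as.matrix(res[, c("x", "y", "z")])
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
  geom <- center_of_interface(interface)
  ddg <- res$ddg
  max_abs <- suppressWarnings(max(abs(ddg), na.rm = TRUE))
  ddg_norm <- if (is.finite(max_abs) && max_abs > 0) ddg / max_abs else ddg
  max_dr <- max(geom$dr)
  out <- data.frame(chain = res$chain, resseq = res$resseq, icode = res$icode,
                    pc1 = pc$x[, 1L], pc2 = pc$x[, 2L],
                    dr = geom$dr,
                    dr_norm = if (max_dr > 0) geom$dr / max_dr else geom$dr,
                    ddg = ddg, ddg_norm = ddg_norm,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "axis2_defined") <- pc$sdev[2L] > 1e-8 * max(pc$sdev[1L], 1e-300)
  out
}
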