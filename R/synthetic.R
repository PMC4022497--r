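# Synthetic interface generator: radially organised FLIP-like patches
# (ddG decaying linearly with distance from the interface centre) and
# FunC-like patches (no radial energy correlation, lower overall ddG),
# with ground-truth parameters for recovery tests, plus writers that emit
# the same PDB / ddG-table files the input layer consumes.

#' Parameters of the synthetic interface generator
#'
#' @param n_residues Number of interfacial residues; `NULL` (default) draws
#'   uniformly from 10 to 40 per interface.
#' @param radius_scale Radius of the interface disc, in angstroms
#'   (default 10).
#' @param flip_intercept Central ddG of a FLIP-like interface, kcal/mol
#'   (default +2.0).
#' @param flip_slope Radial ddG decay of a FLIP-like interface, kcal/mol/A
#'   (default -0.15).
#' @param func_mean_ddg Mean ddG of a FunC-like interface, kcal/mol
#'   (default +0.3).
#' @param noise_sd Gaussian ddG noise, kcal/mol (default 0.5).
#' @param hot_threshold Hotspot threshold, kcal/mol (default +1.0).
#' @param jitter_z_sd Out-of-plane positional jitter, angstroms (default 1).
#' @param simulate_glypro If `TRUE`, roughly 10% of residues are drawn as
#'   Gly/Pro and carry a missing ddG, emulating the alanine-scan masking.
#' @return A validated list of class `ecr_sim_params`.
#' @export
ecr_sim_params <- function(n_residues = NULL, radius_scale = 10,
                           flip_intercept = 2.0, flip_slope = -0.15,
                           func_mean_ddg = 0.3, noise_sd = 0.5,
                           hot_threshold = 1.0, jitter_z_sd = 1.0,
                           simulate_glypro = FALSE) {
  p <- list(n_residues = n_residues, radius_scale = radius_scale,
            flip_intercept = flip_intercept, flip_slope = flip_slope,
            func_mean_ddg = func_mean_ddg, noise_sd = noise_sd,
            hot_threshold = hot_threshold, jitter_z_sd = jitter_z_sd,
            simulate_glypro = isTRUE(simulate_glypro))
  if (!is.null(p$n_residues) &&
      (!is.numeric(p$n_residues) || p$n_residues < 3)) {
    stop_input("n_residues must be at least 3")
  }
  if (!is.numeric(p$radius_scale) || p$radius_scale <= 0) {
    stop_input("radius_scale must be positive")
  }
  if (!is.numeric(p$noise_sd) || p$noise_sd < 0) {
    stop_input("noise_sd must be non-negative")
  }
  structure(p, class = "ecr_sim_params")
}

# Build one synthetic interface from the current RNG stream.
.gen_interface <- function(params, category, id) {
  n <- params$n_residues %||% sample(10:40, 1L)
  n <- as.integer(n)
  # residue positions ~ uniform over a disc, with small out-of-plane jitter;
  # coordinates are rounded to PDB precision (0.001 A) at generation time so
  # that writing and re-reading the structure is lossless.
  r <- params$radius_scale * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  xyz <- round(cbind(x = r * cos(th), y = r * sin(th),
                     z = stats::rnorm(n, 0, params$jitter_z_sd)), 3L)
  chain <- sample(rep(c("A", "B"), length.out = n))
  resseq <- integer(n)
  for (ch in c("A", "B")) resseq[chain == ch] <- seq_len(sum(chain == ch))

  pool <- setdiff(STANDARD_AA, c("GLY", "PRO"))
  resname <- sample(pool, n, replace = TRUE)
  if (params$simulate_glypro) {
    gp <- stats::runif(n) < 0.10
    resname[gp] <- sample(c("GLY", "PRO"), sum(gp), replace = TRUE)
  }

  coi <- colMeans(xyz)
  dr <- sqrt(rowSums(sweep(xyz, 2L, coi)^2))
  noise <- stats::rnorm(n, 0, params$noise_sd)
  if (category == "FLIP") {
    ddg <- params$flip_intercept + params$flip_slope * dr + noise
    true_params <- list(intercept = params$flip_intercept,
                        slope = params$flip_slope,
                        noise_sd = params$noise_sd)
  } else {
    ddg <- params$func_mean_ddg + noise
    true_params <- list(intercept = params$func_mean_ddg, slope = 0,
                        noise_sd = params$noise_sd)
  }
  ddg[resname %in% c("GLY", "PRO")] <- NA_real_

  interface <- structure(
    list(id = id, pdb_id = id, chain_a = "A", chain_b = "B", cutoff = Inf,
         residues = data.frame(chain = chain, resseq = resseq, icode = "",
                               resname = resname,
                               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                               backbone_complete = TRUE, nonstandard = FALSE,
                               ddg = ddg, stringsAsFactors = FALSE),
         category = category, subcategory = "synthetic",
         het_near = FALSE, het_near_names = character(0)),
    class = "ecr_interface")
  structure(list(interface = interface, true_category = category,
                 true_params = true_params),
            class = "ecr_synth")
}

#' Generate one synthetic FLIP-like interface
#'
#' Residues are placed approximately uniformly over a disc of radius
#' `radius_scale` (with small out-of-plane jitter) and assigned
#' `ddG = flip_intercept + flip_slope * dr + N(0, noise_sd)`, where `dr` is
#' the distance from the empirical centre of interface -- the radially
#' organised energetics characteristic of a functionally linked interface.
#'
#' @param params An [ecr_sim_params()] object.
#' @param seed Optional integer seed for a deterministic draw.
#' @param id Interface identifier.
#' @return An object of class `ecr_synth`: list with `interface`
#'   (`ecr_interface`), `true_category`, and `true_params` (the generating
#'   intercept/slope/noise).
#' @export
generate_flip <- function(params = ecr_sim_params(), seed = NULL,
                          id = "synthflip_AB") {
  stopifnot(inherits(params, "ecr_sim_params"))
  if (!is.null(seed)) with_seed(seed, .gen_interface(params, "FLIP", id))
  else .gen_interface(params, "FLIP", id)
}

#' Generate one synthetic FunC-like interface
#'
#' Same spatial process as [generate_flip()], but
#' `ddG = N(func_mean_ddg, noise_sd)` independent of the distance from the
#' centre: no radial energy correlation, lower overall ddG, and few hot
#' residues.
#'
#' @inheritParams generate_flip
#' @return An `ecr_synth` with `true_category = "FunC"`.
#' @export
generate_func <- function(params = ecr_sim_params(), seed = NULL,
                          id = "synthfunc_AB") {
  stopifnot(inherits(params, "ecr_sim_params"))
  if (!is.null(seed)) with_seed(seed, .gen_interface(params, "FunC", id))
  else .gen_interface(params, "FunC", id)
}

#' Generate a labeled synthetic training dataset
#'
#' Draws `n_flip` FLIP-like and `n_func` FunC-like interfaces whose
#' generating parameters are jittered around the defaults (intercepts
#' `N(flip_intercept, 0.5)`, slopes `N(flip_slope, 0.05)`, FunC means
#' `N(func_mean_ddg, 0.15)`), computes the eight features for each, and
#' attaches the true labels.  Fully deterministic given `seed`.
#'
#' @param n_flip,n_func Numbers of FLIP-like and FunC-like interfaces
#'   (default 100 and 60, the composition of the reference training set).
#' @param params Base [ecr_sim_params()].
#' @param seed Integer seed (default 1).
#' @return A list of class `ecr_sim_dataset`: `features` (data frame, one
#'   row per interface with `id`, `category` = true label, `subcategory`
#'   and the eight features) and `interfaces` (list of `ecr_synth`).
#' @export
generate_dataset <- function(n_flip = 100L, n_func = 60L,
                             params = ecr_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "ecr_sim_params"))
  if (n_flip + n_func < 6L) stop_input("dataset needs at least 6 interfaces")
  categories <- c(rep("FLIP", n_flip), rep("FunC", n_func))
  interfaces <- with_seed(seed, {
    lapply(seq_along(categories), function(i) {
      cat_i <- categories[i]
      p <- params
      if (cat_i == "FLIP") {
        p$flip_intercept <- stats::rnorm(1L, params$flip_intercept, 0.5)
        p$flip_slope <- stats::rnorm(1L, params$flip_slope, 0.05)
      } else {
        p$func_mean_ddg <- stats::rnorm(1L, params$func_mean_ddg, 0.15)
      }
      id <- sprintf("synth%s%03d_AB", tolower(cat_i), i)
      .gen_interface(p, cat_i, id)
    })
  })
  features <- ecr_feature_table(interfaces,
                                hot_threshold = params$hot_threshold)
  structure(list(features = features, interfaces = interfaces,
                 seed = as.integer(seed)),
            class = "ecr_sim_dataset")
}

#' @export
print.ecr_sim_dataset <- function(x, ...) {
  tab <- table(x$features$category)
  cat("Synthetic interface dataset: ",
      paste(sprintf("%d %s", tab, names(tab)), collapse = " + "),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic interface as PDB + ddG table files
#'
#' Emits the PDB-format coordinate file (N, CA, C, O backbone records built
#' around the generated C-alpha positions) and the tab-separated ddG table
#' that [read_structure()] / [read_ddg_table()] consume, enabling full
#' round-trip tests of the input layer.  ddG values are written with 17
#' significant digits and coordinates were generated at PDB precision, so
#' re-reading reproduces the features exactly.
#'
#' @param synth An `ecr_synth` (or `ecr_interface`).
#' @param dir Output directory.
#' @return Named character vector with the `pdb` and `ddg` file paths.
#' @export
write_synthetic <- function(synth, dir = tempdir()) {
  interface <- if (inherits(synth, "ecr_synth")) synth$interface else synth
  stopifnot(inherits(interface, "ecr_interface"))
  res <- interface$residues
  n <- nrow(res)
  # fabricate backbone positions around each C-alpha so the disorder filter
  # sees complete residues; geometry-bearing atoms are the C-alphas only
  offs <- list(N = c(-1.2, 0.3, 0), CA = c(0, 0, 0),
               C = c(1.2, 0.3, 0), O = c(1.9, -0.6, 0))
  elety <- rep(names(offs), times = n)
  idx <- rep(seq_len(n), each = 4L)
  xyz <- t(vapply(seq_along(idx), function(k) {
    as.numeric(res[idx[k], c("x", "y", "z")]) + offs[[elety[k]]]
  }, numeric(3L)))
  pdb_path <- file.path(dir, paste0(interface$pdb_id, ".pdb"))
  bio3d::write.pdb(file = pdb_path, xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", length(idx)),
                   resno = res$resseq[idx], resid = res$resname[idx],
                   chain = res$chain[idx], elety = elety,
                   eleno = seq_along(idx), o = rep(1, length(idx)),
                   b = rep(0, length(idx)))
  ddg_path <- file.path(dir, paste0(interface$pdb_id, "_ddg.tsv"))
  keep <- is.finite(res$ddg)
  tab <- data.frame(chain = res$chain[keep], res = res$resseq[keep],
                    icode = ifelse(nzchar(res$icode[keep]), res$icode[keep], "-"),
                    resname = res$resname[keep],
                    ddg = sprintf("%.17g", res$ddg[keep]),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, ddg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(pdb = pdb_path, ddg = ddg_path)
}
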