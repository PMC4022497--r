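# Internal helpers: condition classes, RNG hygiene, formatting.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecr_input_error", "error", "condition")))
}

#' @noRd
stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecr_degenerate_error", "error", "condition")))
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  Keeps package randomness reproducible
# without clobbering user code.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Round-half-up, used for percent display ("76.25%" prints as "76.3%").
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_pct <- function(x) sprintf("%.1f%%", round_half_up(100 * x, 1))

# Canonical feature order used throughout: 8 features, r2_ddg is the one
# dropped before classification.
ECR_FEATURES <- c("slope_ddg", "intcpt_ddg", "r2_ddg", "sum_ddg",
                  "avg_ddg", "n_total", "n_hot", "frac_hot")

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

WATER_RESID <- c("HOH", "WAT", "DOD")

# Monoatomic "simple ions" tolerated near an interface; any other
# heteroatom group triggers rejection.
SIMPLE_IONS <- c("NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE")
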