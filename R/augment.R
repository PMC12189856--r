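# Feature-level data augmentation: each channels x features instance is
# expanded with synthetic variants produced by (1) additive zero-mean
# Gaussian noise, (2) a single uniform amplitude scaling, and (3) dynamic
# modulation of each entry's deviation from the instance mean, re-centered
# so the parent instance's mean is preserved exactly.

#' Augmentation settings
#'
#' Defaults follow the standard feature-level recipe: noise SD 0.05,
#' scaling range \[0.9, 1.1\], 50 synthetic variants per original (a 51x
#' expansion).
#'
#' @param noise_sd SD of additive zero-mean Gaussian noise, on the feature
#'   scale (absolute). Set `standardized = TRUE` to apply it on per-feature
#'   z-scores instead, which is less scale-sensitive across heterogeneous
#'   features.
#' @param scale_low,scale_high Uniform amplitude-scaling range.
#' @param n_variants Synthetic variants per original instance (default 50).
#' @param modulation_strength Magnitude bound of the uniform per-entry
#'   modulation of deviations from the instance mean (dimensionless
#'   fraction; default 0.1).
#' @param standardized Apply the noise step on per-feature standardized
#'   values (default FALSE: absolute scale, as is conventional).
#' @param seed Integer seed; augmentation is deterministic given the seed.
#' @return A `ctesm_augmentation_spec`.
#' @export
augmentation_spec <- function(noise_sd = 0.05, scale_low = 0.9,
                              scale_high = 1.1, n_variants = 50,
                              modulation_strength = 0.1,
                              standardized = FALSE, seed = 1L) {
  check_positive_scalar(noise_sd, "noise_sd", allow_zero = TRUE)
  check_positive_scalar(n_variants, "n_variants", integer = TRUE)
  check_positive_scalar(modulation_strength, "modulation_strength",
                        allow_zero = TRUE)
  if (!is.numeric(scale_low) || !is.numeric(scale_high) ||
      scale_low > scale_high) {
    stop_validation("fields 'scale_low'/'scale_high' must satisfy low <= high")
  }
  structure(
    list(noise_sd = noise_sd, scale_low = scale_low, scale_high = scale_high,
         n_variants = as.integer(n_variants),
         modulation_strength = modulation_strength,
         standardized = isTRUE(standardized), seed = as.integer(seed)),
    class = "ctesm_augmentation_spec"
  )
}

#' Expand a feature-instance set with synthetic variants
#'
#' For each original instance `X` the output contains `X` unchanged followed
#' by `n_variants` synthetic matrices. Each variant is built by:
#' noise addition, uniform scaling, then modulation
#' `Y <- X' + g * (X' - mean(X'))` with `g ~ U(-strength, strength)` per
#' entry, finally re-centered to the parent's mean. Labels are inherited
#' from the parent; provenance is recorded per instance.
#'
#' @param instances Non-empty list of `ctesm_features`.
#' @param spec An [augmentation_spec()].
#' @return A `ctesm_augmented` list with elements `instances` (ordered
#'   list, originals followed by their variants), `is_synthetic` (logical
#'   per instance) and `parent_id` (index of the parent original, `NA` for
#'   originals).
#' @export
#' @examples
#' # identity configuration reproduces each parent exactly
#' spec <- augmentation_spec(noise_sd = 0, scale_low = 1, scale_high = 1,
#'                           n_variants = 2, modulation_strength = 0)
augment <- function(instances, spec = augmentation_spec()) {
  if (!length(instances)) {
    stop_validation("'instances' must be a non-empty list of feature instances")
  }
  if (!inherits(spec, "ctesm_augmentation_spec")) {
    stop_validation("'spec' must be created by augmentation_spec()")
  }
  n0 <- length(instances)
  k <- spec$n_variants
  out <- vector("list", n0 * (k + 1L))
  synth <- logical(n0 * (k + 1L))
  parent <- rep(NA_integer_, n0 * (k + 1L))

  feat_sd <- NULL
  if (spec$standardized) {
    arr <- vapply(instances, function(i) i$matrix,
                  instances[[1]]$matrix)
    feat_sd <- apply(arr, 2, stats::sd)
    feat_sd[feat_sd == 0] <- 1
  }

  pos <- 0L
  for (i in seq_len(n0)) {
    inst <- instances[[i]]
    pos <- pos + 1L
    out[[pos]] <- inst
    with_seed(derive_seed(spec$seed, i), {
      X <- inst$matrix
      mu0 <- mean(X)
      dims <- dim(X)
      for (v in seq_len(k)) {
        noise <- matrix(stats::rnorm(prod(dims), sd = spec$noise_sd),
                        dims[1], dims[2])
        if (spec$standardized) {
          noise <- sweep(noise, 2, feat_sd, "*")
        }
        Xp <- (X + noise) * stats::runif(1, spec$scale_low, spec$scale_high)
        g <- matrix(stats::runif(prod(dims), -spec$modulation_strength,
                                 spec$modulation_strength),
                    dims[1], dims[2])
        Y <- Xp + g * (Xp - mean(Xp))
        Y <- Y - mean(Y) + mu0
        pos <- pos + 1L
        out[[pos]] <- new_feature_instance(
          Y, inst$feature_names, inst$label, inst$subject_id,
          inst$frame_index)
        synth[pos] <- TRUE
        parent[pos] <- i
      }
    })
  }
  structure(list(instances = out, is_synthetic = synth, parent_id = parent),
            class = "ctesm_augmented")
}

#' @export
print.ctesm_augmented <- function(x, ...) {
  cat(sprintf("<ctesm_augmented> %d instances (%d original, %d synthetic)\n",
              length(x$instances), sum(!x$is_synthetic), sum(x$is_synthetic)))
  invisible(x)
}
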