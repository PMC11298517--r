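# Multiscale 2D feature bank for trainable pixel classification,
# mirroring the classic trainable-segmentation feature families:
# Gaussian smoothing over a power-of-two sigma ladder, Gaussian
# gradient magnitude, Hessian eigenvalues, differences of Gaussians,
# and rotated-line membrane projections.
#
# Filtering is FFT-based: each slice is replicate-padded and
# transformed once, then multiplied by cached kernel frequency
# responses (which depend only on slice shape and configuration), so
# filtering whole volumes costs one forward and one inverse transform
# per slice and filter.

#' Feature bank configuration
#'
#' Defines the multiscale filter bank computed per slice. The sigma set
#' is the power-of-two ladder `{1, 2, 4, ...} <= max_sigma`, plus sigma
#' 0 (the unfiltered image) when `min_sigma = 0`. The defaults mirror a
#' field-of-view setting of min sigma 0.0 / max sigma 16.0 with membrane
#' thickness 1 and patch size 19.
#'
#' @param min_sigma smallest scale; 0 includes the raw image.
#' @param max_sigma largest Gaussian scale in pixels.
#' @param features character subset of `"gaussian"`,
#'   `"gradient_magnitude"`, `"hessian_eigenvalues"`,
#'   `"difference_of_gaussians"`, `"membrane_projections"`.
#' @param membrane_thickness line thickness (pixels) of the membrane
#'   kernels.
#' @param membrane_patch_size odd kernel size for membrane projections.
#' @param membrane_angles number of line orientations over 180 degrees.
#' @return an object of class `feature_bank_config`; its
#'   `feature_names` field fixes the bank composition and order.
#' @export
feature_bank_config <- function(min_sigma = 0,
                                max_sigma = 16,
                                features = c("gaussian",
                                             "gradient_magnitude",
                                             "hessian_eigenvalues",
                                             "difference_of_gaussians",
                                             "membrane_projections"),
                                membrane_thickness = 1L,
                                membrane_patch_size = 19L,
                                membrane_angles = 30L) {
  known <- c("gaussian", "gradient_magnitude", "hessian_eigenvalues",
             "difference_of_gaussians", "membrane_projections")
  bad <- setdiff(features, known)
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (max_sigma < min_sigma) stop("max_sigma < min_sigma", call. = FALSE)
  if (max_sigma <= 0) stop("max_sigma must be positive", call. = FALSE)
  if (membrane_patch_size %% 2L == 0L)
    stop("membrane_patch_size must be odd", call. = FALSE)
  base <- if (min_sigma > 0) min_sigma else 1
  sigmas <- base * 2^(0:floor(log2(max_sigma / base)))
  sigma_set <- c(if (min_sigma == 0) 0, sigmas)
  cfg <- structure(list(min_sigma = min_sigma, max_sigma = max_sigma,
                        sigma_set = sigma_set, features = features,
                        membrane_thickness = as.integer(membrane_thickness),
                        membrane_patch_size = as.integer(membrane_patch_size),
                        membrane_angles = as.integer(membrane_angles)),
                   class = "feature_bank_config")
  cfg$feature_names <- feature_names(cfg)
  cfg
}

.fmt_sigma <- function(x) sub("\\.0+$", "", format(x, trim = TRUE))

#' Names of the features produced by a configuration
#'
#' Deterministic enumeration of the feature bank; the length of this
#' vector is the reported feature count.
#'
#' @param config a `feature_bank_config`.
#' @return character vector of feature names, in computation order.
#' @export
feature_names <- function(config) {
  s <- config$sigma_set
  pos <- s[s > 0]
  out <- character(0)
  if ("gaussian" %in% config$features)
    out <- c(out, paste0("gaussian_s", .fmt_sigma(s)))
  if ("gradient_magnitude" %in% config$features)
    out <- c(out, paste0("gradmag_s", .fmt_sigma(pos)))
  if ("hessian_eigenvalues" %in% config$features)
    out <- c(out, as.vector(rbind(paste0("hessian1_s", .fmt_sigma(pos)),
                                  paste0("hessian2_s", .fmt_sigma(pos)))))
  if ("difference_of_gaussians" %in% config$features && length(s) >= 2) {
    pr <- utils::combn(s, 2)
    out <- c(out, paste0("dog_s", .fmt_sigma(pr[1, ]),
                         "_s", .fmt_sigma(pr[2, ])))
  }
  if ("membrane_projections" %in% config$features)
    out <- c(out, paste0("membrane_", c("sum", "mean", "max", "min",
                                        "median", "sd")))
  out
}

#' @export
print.feature_bank_config <- function(x, ...) {
  cat(sprintf("<feature_bank_config> sigmas {%s} | %d features: %s\n",
              paste(x$sigma_set, collapse = ", "),
              length(x$feature_names),
              paste(x$features, collapse = ", ")))
  invisible(x)
}

# 1D Gaussian and derivatives sampled on integer offsets -r..r
.g0 <- function(sigma, r) {
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}
.g1 <- function(sigma, r) {
  x <- -r:r
  -x / sigma^2 * exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}
.g2 <- function(sigma, r) {
  x <- -r:r
  (x^2 - sigma^2) / sigma^4 * exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

# rotated-line kernel: patch x patch, ones within thickness of the
# center line at the given angle, clipped to the patch half-length
.line_kernel <- function(patch, thickness, theta) {
  h <- (patch - 1) / 2
  idx <- -h:h
  yy <- matrix(idx, patch, patch)
  xx <- t(yy)
  dist_line <- abs(-sin(theta) * xx + cos(theta) * yy)
  along <- abs(cos(theta) * xx + sin(theta) * yy)
  k <- (dist_line <= thickness / 2 + 0.5) & (along <= h + 0.5)
  storage.mode(k) <- "double"
  k
}

# embed a centered (2r+1) x (2r+1) kernel into an N1 x N2 array with its
# center wrapped to index (1,1), and return its FFT
.kernel_fft <- function(K, N1, N2) {
  r1 <- (nrow(K) - 1L) %/% 2L
  r2 <- (ncol(K) - 1L) %/% 2L
  big <- matrix(0, N1, N2)
  ri <- ((-r1:r1) %% N1) + 1L
  ci <- ((-r2:r2) %% N2) + 1L
  big[ri, ci] <- K
  fft(big)
}

# cache of filter plans keyed by slice shape + config fingerprint
.fb_cache <- new.env(parent = emptyenv())

.plan_key <- function(d, config) {
  paste(d[1], d[2], config$min_sigma, config$max_sigma,
        paste(sort(config$features), collapse = "+"),
        config$membrane_thickness, config$membrane_patch_size,
        config$membrane_angles, sep = "|")
}

# build (or fetch) the filter plan: pad width and kernel FFTs
.fb_plan <- function(d, config) {
  key <- .plan_key(d, config)
  if (!is.null(.fb_cache[[key]])) return(.fb_cache[[key]])
  cap <- (min(d) - 1L) %/% 2L
  rad <- function(sigma) as.integer(max(1, min(ceiling(3 * sigma), cap)))
  pos <- config$sigma_set[config$sigma_set > 0]
  patch <- min(config$membrane_patch_size, 2L * cap + 1L)
  pads <- c(1L, if (length(pos)) vapply(pos, rad, integer(1)),
            if ("membrane_projections" %in% config$features) (patch - 1L) %/% 2L)
  p <- max(pads)
  N1 <- d[1] + 2L * p; N2 <- d[2] + 2L * p
  K <- list()
  need_gauss <- any(c("gaussian", "difference_of_gaussians") %in% config$features)
  for (sg in pos) {
    r <- rad(sg)
    if (need_gauss)
      K[[paste0("g0g0_", sg)]] <- .kernel_fft(outer(.g0(sg, r), .g0(sg, r)), N1, N2)
    if ("gradient_magnitude" %in% config$features) {
      K[[paste0("g1g0_", sg)]] <- .kernel_fft(outer(.g1(sg, r), .g0(sg, r)), N1, N2)
      K[[paste0("g0g1_", sg)]] <- .kernel_fft(outer(.g0(sg, r), .g1(sg, r)), N1, N2)
    }
    if ("hessian_eigenvalues" %in% config$features) {
      K[[paste0("g2g0_", sg)]] <- .kernel_fft(outer(.g2(sg, r), .g0(sg, r)), N1, N2)
      K[[paste0("g0g2_", sg)]] <- .kernel_fft(outer(.g0(sg, r), .g2(sg, r)), N1, N2)
      K[[paste0("g1g1_", sg)]] <- .kernel_fft(outer(.g1(sg, r), .g1(sg, r)), N1, N2)
    }
  }
  if ("membrane_projections" %in% config$features) {
    thetas <- pi * (seq_len(config$membrane_angles) - 1) / config$membrane_angles
    for (i in seq_along(thetas))
      K[[paste0("memb_", i)]] <-
        .kernel_fft(.line_kernel(patch, config$membrane_thickness, thetas[i]),
                    N1, N2)
  }
  plan <- list(pad = p, N1 = N1, N2 = N2, K = K)
  .fb_cache[[key]] <- plan
  plan
}

# replicate-pad a matrix by p on every side
.pad_replicate <- function(x, p) {
  d <- dim(x)
  x[c(rep(1L, p), seq_len(d[1]), rep(d[1], p)),
    c(rep(1L, p), seq_len(d[2]), rep(d[2], p))]
}

#' Compute the multiscale feature bank of one slice
#'
#' Produces one filtered image per enabled feature and applicable sigma:
#' Gaussian smoothing (sigma 0 = raw image), Gaussian gradient
#' magnitude, the two ordered Hessian eigenvalues, differences of
#' Gaussians for all sigma pairs, and membrane projections (a line
#' kernel of the configured thickness rotated across the patch, with the
#' rotation stack aggregated by sum/mean/max/min/median/sd). Kernel
#' supports are truncated when they would exceed the slice.
#'
#' @param slice 2D numeric matrix (y, x), finite.
#' @param config a [feature_bank_config()].
#' @return 3D array `(y, x, feature)` with feature names on the third
#'   dimension, in the order of `feature_names(config)`.
#' @export
compute_feature_bank <- function(slice, config = feature_bank_config()) {
  stopifnot(is.matrix(slice))
  if (any(!is.finite(slice))) stop("slice must be finite", call. = FALSE)
  d <- dim(slice)
  plan <- .fb_plan(d, config)
  Fimg <- fft(.pad_replicate(slice, plan$pad))
  nn <- plan$N1 * plan$N2
  rows <- plan$pad + seq_len(d[1])
  cols <- plan$pad + seq_len(d[2])
  conv <- function(name)
    Re(fft(Fimg * plan$K[[name]], inverse = TRUE))[rows, cols] / nn
  s <- config$sigma_set
  pos <- s[s > 0]
  nmv <- config$feature_names
  out <- array(0, dim = c(d[1], d[2], length(nmv)),
               dimnames = list(NULL, NULL, nmv))
  put <- function(name, img) out[, , name] <<- img
  smoothed <- list()
  get_smooth <- function(sg) {
    key <- as.character(sg)
    if (is.null(smoothed[[key]]))
      smoothed[[key]] <<- if (sg == 0) slice else conv(paste0("g0g0_", sg))
    smoothed[[key]]
  }
  if ("gaussian" %in% config$features)
    for (sg in s) put(paste0("gaussian_s", .fmt_sigma(sg)), get_smooth(sg))
  if ("gradient_magnitude" %in% config$features)
    for (sg in pos) {
      gy <- conv(paste0("g1g0_", sg))
      gx <- conv(paste0("g0g1_", sg))
      put(paste0("gradmag_s", .fmt_sigma(sg)), sqrt(gy^2 + gx^2))
    }
  if ("hessian_eigenvalues" %in% config$features)
    for (sg in pos) {
      iyy <- conv(paste0("g2g0_", sg))
      ixx <- conv(paste0("g0g2_", sg))
      ixy <- conv(paste0("g1g1_", sg))
      tr2 <- (ixx + iyy) / 2
      disc <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
      put(paste0("hessian1_s", .fmt_sigma(sg)), tr2 + disc)
      put(paste0("hessian2_s", .fmt_sigma(sg)), tr2 - disc)
    }
  if ("difference_of_gaussians" %in% config$features && length(s) >= 2) {
    pr <- utils::combn(s, 2)
    for (j in seq_len(ncol(pr)))
      put(paste0("dog_s", .fmt_sigma(pr[1, j]), "_s", .fmt_sigma(pr[2, j])),
          get_smooth(pr[1, j]) - get_smooth(pr[2, j]))
  }
  if ("membrane_projections" %in% config$features) {
    n_ang <- config$membrane_angles
    M <- matrix(0, prod(d), n_ang)
    for (i in seq_len(n_ang)) M[, i] <- conv(paste0("memb_", i))
    sums <- rowSums(M)
    put("membrane_sum", matrix(sums, d[1], d[2]))
    put("membrane_mean", matrix(sums / n_ang, d[1], d[2]))
    mx <- M[, 1]; mn <- M[, 1]
    for (i in seq_len(n_ang)[-1]) { mx <- pmax(mx, M[, i]); mn <- pmin(mn, M[, i]) }
    put("membrane_max", matrix(mx, d[1], d[2]))
    put("membrane_min", matrix(mn, d[1], d[2]))
    Msort <- matrix(M[order(row(M), M)], nrow = nrow(M), byrow = TRUE)
    med <- if (n_ang %% 2L == 1L) Msort[, (n_ang + 1L) %/% 2L]
           else (Msort[, n_ang %/% 2L] + Msort[, n_ang %/% 2L + 1L]) / 2
    put("membrane_median", matrix(med, d[1], d[2]))
    sdv <- sqrt(pmax(rowSums(M^2) - sums^2 / n_ang, 0) / (n_ang - 1))
    put("membrane_sd", matrix(sdv, d[1], d[2]))
  }
  out
}
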