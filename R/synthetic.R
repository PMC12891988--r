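#' Configure a synthetic bimodal cohort
#'
#' Describes a linear-Gaussian generative model for coupled two-modality
#' embedding cohorts with known class structure, emulating paired
#' whole-slide-image and immune-repertoire embeddings: each patient of
#' class c draws a shared latent factor `z ~ N(mu_c, I_s)` and the two
#' observed embeddings are noisy linear images of the same z. Class means
#' `mu_c` sit at distinct vertices of the `±class_sep` hypercube in the
#' s-dimensional latent space, so classes are separated by at least
#' `2 * class_sep` (and typically by `2 * class_sep * sqrt(s/2)`).
#'
#' In `coupling = "independent"` mode the sequence modality uses a latent
#' redrawn under a random permutation of the cohort's class assignments:
#' its marginal distribution is unchanged but it carries no cross-modal
#' coupling (and no label signal), which is the null condition for the
#' cross-reconstruction coherence check.
#'
#' @param n_classes number of diagnosis classes (default 3, a
#'   three-subtype cohort).
#' @param n_per_class patients per class; a scalar or a length-`n_classes`
#'   vector for imbalanced cohorts (default 100).
#' @param d_f,d_g embedding dimensions (default 768, typical transformer
#'   backbone width).
#' @param shared_dim s, the shared latent factor size (default 16).
#' @param class_sep per-coordinate class mean shift magnitude (default 2).
#' @param noise_sd standard deviation of the additive embedding noise
#'   (default 0.5).
#' @param coupling `"coupled"` or `"independent"`.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param class_names optional class labels (default `class_1`, ...).
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_classes = 3L, n_per_class = 100L,
                             d_f = 768L, d_g = 768L, shared_dim = 16L,
                             class_sep = 2, noise_sd = 0.5,
                             coupling = c("coupled", "independent"),
                             seed = 1L, class_names = NULL) {
  coupling <- match.arg(coupling)
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 1, all(n_per_class >= 1), d_f >= 1, d_g >= 1,
            shared_dim >= 1, class_sep >= 0, noise_sd >= 0)
  if (length(n_per_class) == 1L) {
    n_per_class <- rep(as.integer(n_per_class), n_classes)
  }
  if (length(n_per_class) != n_classes) {
    stop("n_per_class must be scalar or length n_classes")
  }
  if (n_classes > 2^shared_dim) {
    stop("cannot place ", n_classes, " distinct class means in a ",
         shared_dim, "-dimensional hypercube")
  }
  if (is.null(class_names)) {
    class_names <- paste0("class_", seq_len(n_classes))
  }
  stopifnot(length(class_names) == n_classes)
  structure(
    list(n_classes = n_classes, n_per_class = as.integer(n_per_class),
         d_f = as.integer(d_f), d_g = as.integer(d_g),
         shared_dim = as.integer(shared_dim), class_sep = class_sep,
         noise_sd = noise_sd, coupling = coupling,
         seed = as.integer(seed), class_names = class_names),
    class = "synthetic_config"
  )
}

#' Generate a synthetic bimodal cohort
#'
#' Draws a cohort under a [synthetic_config()]: distinct hypercube-vertex
#' class means `mu_c`, per-patient shared latents `z ~ N(mu_c, I)`, fixed
#' mixing maps `A` (d_f x s) and `B` (d_g x s) with `N(0, 1/s)` entries
#' drawn once per cohort, and embeddings `f = A z + eps_f`,
#' `g = B z + eps_g` with `eps ~ N(0, noise_sd^2)`. Bit-identical given
#' the config seed.
#'
#' @param config a [synthetic_config()].
#' @return A [new_cohort()] with attribute `"ground_truth"`: a list with
#'   the latent matrix `z` (or `z_g` for the decoupled sequence latent),
#'   `class_means`, mixing maps `A`, `B`, and the config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  n <- sum(cf$n_per_class)
  labels <- rep(cf$class_names, times = cf$n_per_class)
  ids <- sprintf("P%04d", seq_len(n))
  with_seed(cf$seed, {
    # distinct hypercube vertices as class means
    repeat {
      Mu <- matrix(sample(c(-1, 1), cf$n_classes * cf$shared_dim,
                          replace = TRUE),
                   cf$n_classes, cf$shared_dim) * cf$class_sep
      if (cf$class_sep == 0 ||
          nrow(unique(Mu)) == cf$n_classes) break
    }
    A <- matrix(rnorm(cf$d_f * cf$shared_dim, sd = 1 / sqrt(cf$shared_dim)),
                cf$d_f, cf$shared_dim)
    B <- matrix(rnorm(cf$d_g * cf$shared_dim, sd = 1 / sqrt(cf$shared_dim)),
                cf$d_g, cf$shared_dim)
    cls <- rep(seq_len(cf$n_classes), times = cf$n_per_class)
    z <- Mu[cls, , drop = FALSE] +
      matrix(rnorm(n * cf$shared_dim), n, cf$shared_dim)
    f <- z %*% t(A) +
      matrix(rnorm(n * cf$d_f, sd = cf$noise_sd), n, cf$d_f)
    if (cf$coupling == "coupled") {
      z_g <- z
    } else {
      # redraw the sequence latent under permuted class assignments:
      # identical marginals, no coupling with f and no label signal
      cls_perm <- cls[sample.int(n)]
      z_g <- Mu[cls_perm, , drop = FALSE] +
        matrix(rnorm(n * cf$shared_dim), n, cf$shared_dim)
    }
    g <- z_g %*% t(B) +
      matrix(rnorm(n * cf$d_g, sd = cf$noise_sd), n, cf$d_g)
    coh <- new_cohort(ids, labels, f, g)
    attr(coh, "ground_truth") <- list(z = z, z_g = z_g, class_means = Mu,
                                      A = A, B = B, config = cf)
    coh
  })
}

#' Within- vs between-class separation per modality
#'
#' For each modality, the ratio of the mean within-class pairwise
#' Euclidean distance to the mean between-class pairwise distance. A
#' ratio near 1 means no class structure; ratios well below 1 mean tight,
#' well-separated classes. Used to calibrate synthetic configs.
#'
#' @param cohort a cohort.
#' @param labels class assignment per patient (defaults to the cohort's
#'   labels; pass a permutation as a negative control).
#' @return Named numeric vector `c(f = ratio_f, g = ratio_g)`.
#' @export
cohort_separability <- function(cohort, labels = cohort$label) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("separability needs at least 2 classes")
  }
  ratio_for <- function(X) {
    D <- as.matrix(stats::dist(X))
    same <- outer(labels, labels, "==")
    ut <- upper.tri(D)
    mean(D[ut & same]) / mean(D[ut & !same])
  }
  c(f = ratio_for(cohort$f), g = ratio_for(cohort$g))
}
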