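#' Run the full cross-validated monogram experiment
#'
#' Drives the complete protocol on a cohort: patient-level stratified
#' folds; per fold, min-max scalers, both cross-modal autoencoders and
#' the monogram fusion network are fitted on the training fold \emph{only};
#' the held-out fold is encoded and evaluated leave-one-out at each vote
#' size for four representations -- binary monograms (Hamming), real
#' monograms (Euclidean on the 64 tanh values), and the two unimodal
#' baselines (Euclidean on the min-max-rescaled raw embeddings).
#'
#' Training defaults follow the pipeline's standard settings: the
#' image-to-genomic autoencoder trains 150 epochs at learning rate 1e-5,
#' the genomic-to-image autoencoder 50 epochs at 1e-4, and the fusion
#' network 150 epochs at 1e-5 with hard triplet mining refreshed every
#' epoch. All sub-seeds derive from `seed`, so reruns are bit-identical.
#'
#' @param cohort a [new_cohort()] (e.g. from [generate_cohort()]).
#' @param n_folds number of cross-validation folds (default 2, the
#'   protocol used for three-class cohorts with a rare subtype; use 5 for
#'   large two-class cohorts).
#' @param ks vote sizes evaluated, default `c(1, 3, 5, 10)`.
#' @param seed master seed.
#' @param ae_image,ae_seq optional [autoencoder_spec()] overrides (seeds
#'   are still re-derived per fold).
#' @param mono optional [monogram_spec()] override.
#' @param outdir optional directory; if given, writes `report.json`, per
#'   fold manifests (`fold<i>_{train,test}_ids.csv`), fold archives and
#'   the fold assignment.
#' @param verbose print per-fold progress (default TRUE).
#' @return An object of class `"marblix_experiment"`: list with `folds`
#'   (per-fold reports, manifests, loss curves, archives), `aggregate`
#'   (mean and sd over folds per representation x k x metric), `ks`,
#'   `n_folds`, `seed`.
#' @export
run_experiment <- function(cohort, n_folds = 2L, ks = c(1L, 3L, 5L, 10L),
                           seed = 1L, ae_image = NULL, ae_seq = NULL,
                           mono = NULL, outdir = NULL, verbose = TRUE) {
  stopifnot(inherits(cohort, "cohort"), n_folds >= 2L)
  d_f <- ncol(cohort$f)
  d_g <- ncol(cohort$g)
  if (is.null(ae_image)) {
    ae_image <- autoencoder_spec(d_f, d_g, epochs = 150L,
                                 learning_rate = 1e-5)
  }
  if (is.null(ae_seq)) {
    ae_seq <- autoencoder_spec(d_g, d_f, epochs = 50L,
                               learning_rate = 1e-4)
  }
  if (is.null(mono)) mono <- monogram_spec(latent_dim = ae_image$bottleneck)
  folds <- stratified_folds(cohort, n_folds, seed = derive_seed(seed, 1L))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_folds(folds, file.path(outdir, "folds.csv"))
  }
  reps <- c("binary", "real", "image", "sequence")
  fold_results <- vector("list", n_folds)
  for (fd in seq_len(n_folds)) {
    if (verbose) message("fold ", fd, "/", n_folds)
    test_ids <- names(folds)[folds == fd]
    train_ids <- names(folds)[folds != fd]
    stopifnot(length(intersect(train_ids, test_ids)) == 0L)
    tr <- cohort_subset(cohort, train_ids)
    te <- cohort_subset(cohort, test_ids)

    sc_f <- suppressWarnings(fit_minmax(tr$f, "image"))
    sc_g <- suppressWarnings(fit_minmax(tr$g, "sequence"))
    f_tr <- apply_minmax(tr$f, sc_f)
    g_tr <- apply_minmax(tr$g, sc_g)
    f_te <- apply_minmax(te$f, sc_f)
    g_te <- apply_minmax(te$g, sc_g)

    ai <- ae_image
    ai$seed <- derive_seed(seed, 10L * fd + 2L)
    as_ <- ae_seq
    as_$seed <- derive_seed(seed, 10L * fd + 3L)
    A_I <- train_hybrid_autoencoder(f_tr, g_tr, ai)
    A_S <- train_hybrid_autoencoder(g_tr, f_tr, as_)

    u_tr <- encode_latents(A_I, f_tr)
    v_tr <- encode_latents(A_S, g_tr)
    u_te <- encode_latents(A_I, f_te)
    v_te <- encode_latents(A_S, g_te)

    mq <- mono
    mq$seed <- derive_seed(seed, 10L * fd + 4L)
    Q <- train_monogram_model(u_tr, v_tr, tr$label, mq)

    archive <- encode_monograms(Q, te$patient_id, te$label, u_te, v_te)

    evals <- list(
      binary = leave_one_out_eval(archive, ks, "binary"),
      real = leave_one_out_eval(archive, ks, "real"),
      image = loo_feature_eval(te$patient_id, te$label, f_te, ks),
      sequence = loo_feature_eval(te$patient_id, te$label, g_te, ks)
    )
    if (!is.null(outdir)) {
      data.table::fwrite(data.table::data.table(patient_id = train_ids),
                         file.path(outdir, sprintf("fold%d_train_ids.csv", fd)))
      data.table::fwrite(data.table::data.table(patient_id = test_ids),
                         file.path(outdir, sprintf("fold%d_test_ids.csv", fd)))
      write_archive(archive, file.path(outdir,
                                       sprintf("fold%d_archive.csv", fd)))
    }
    fold_results[[fd]] <- list(
      fold = fd, train_ids = train_ids, test_ids = test_ids,
      evals = evals, archive = archive,
      loss_curves = list(ae_image = A_I$loss_curve,
                         ae_seq = A_S$loss_curve,
                         monogram = Q$loss_curve),
      class_distances = class_distance_summary(archive)
    )
  }
  metric_names <- c("macro_f1", "macro_precision", "macro_recall",
                    "accuracy")
  agg <- list()
  for (rp in reps) {
    per_fold <- lapply(fold_results, function(fr) {
      m <- fr$evals[[rp]]$metrics
      as.matrix(m[, metric_names])
    })
    arr <- simplify2array(per_fold) # k x metric x fold
    agg[[rp]] <- list(
      mean = apply(arr, c(1, 2), mean),
      sd = apply(arr, c(1, 2), sd)
    )
    dimnames(agg[[rp]]$mean) <- dimnames(agg[[rp]]$sd) <-
      list(paste0("k", sort(unique(as.integer(ks)))), metric_names)
  }
  out <- structure(
    list(folds = fold_results, aggregate = agg, ks = sort(unique(ks)),
         n_folds = n_folds, seed = seed,
         specs = list(ae_image = ae_image, ae_seq = ae_seq,
                      monogram = mono)),
    class = "marblix_experiment"
  )
  if (!is.null(outdir)) {
    write_experiment_report(out, file.path(outdir, "report.json"))
  }
  out
}

#' Extract an aggregate metric from an experiment
#'
#' @param experiment a [run_experiment()] result.
#' @param representation one of `"binary"`, `"real"`, `"image"`,
#'   `"sequence"`.
#' @param k vote size.
#' @param metric one of `"macro_f1"`, `"macro_precision"`,
#'   `"macro_recall"`, `"accuracy"`.
#' @return The metric's mean over folds.
#' @export
experiment_metric <- function(experiment, representation, k, metric) {
  experiment$aggregate[[representation]]$mean[paste0("k", k), metric]
}

#' @export
print.marblix_experiment <- function(x, ...) {
  cat("<marblix_experiment> ", x$n_folds, "-fold, seed ", x$seed, "\n",
      sep = "")
  for (rp in names(x$aggregate)) {
    cat("  ", format(rp, width = 9), " accuracy: ",
        paste(sprintf("%s=%.3f", rownames(x$aggregate[[rp]]$mean),
                      x$aggregate[[rp]]$mean[, "accuracy"]),
              collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a machine-readable experiment report
#'
#' One JSON file with per-fold metrics, manifests sizes, loss-curve
#' endpoints, intra/inter class distances, and aggregate mean/sd blocks.
#'
#' @param experiment a [run_experiment()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_experiment_report <- function(experiment, path) {
  fold_block <- lapply(experiment$folds, function(fr) {
    list(
      fold = fr$fold,
      n_train = length(fr$train_ids),
      n_test = length(fr$test_ids),
      metrics = lapply(fr$evals, function(ev) ev$metrics),
      triplet_loss_first = fr$loss_curves$monogram[1],
      triplet_loss_last =
        fr$loss_curves$monogram[length(fr$loss_curves$monogram)],
      class_distances = fr$class_distances
    )
  })
  agg_block <- lapply(experiment$aggregate, function(a) {
    list(mean = as.data.frame(a$mean), sd = as.data.frame(a$sd))
  })
  jsonlite::write_json(
    list(n_folds = experiment$n_folds, seed = experiment$seed,
         ks = experiment$ks, folds = fold_block, aggregate = agg_block),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
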