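# Evaluation: regression metric battery, grouped train/test split, glucose
# banding, ablation bookkeeping and Bland-Altman agreement.

#' Grouped train/test split
#'
#' Seeded shuffle-then-split. By default all segments of one subject land
#' in the same partition (grouped split, preventing leakage between the two
#' conditions of a subject); `grouped = FALSE` restores a plain per-record
#' split. Partition sizes come within one subject of the requested
#' fraction.
#'
#' @param subject_ids Vector of subject identifiers, one per record, or a
#'   data.frame with a `subject_id` column.
#' @param fraction Training fraction (default 0.8).
#' @param seed Non-negative integer seed.
#' @param grouped Keep subjects intact (default `TRUE`).
#' @return List with integer record indices `train` and `test`.
#' @export
split_train_test <- function(subject_ids, fraction = 0.8, seed = 0,
                             grouped = TRUE) {
  if (is.data.frame(subject_ids)) subject_ids <- subject_ids$subject_id
  n <- length(subject_ids)
  if (n < 5L) stop_input("insufficient data: need at least 5 records")
  if (fraction <= 0 || fraction >= 1) {
    stop_input("`fraction` must lie in (0, 1)")
  }
  with_local_seed(seed, {
    if (!grouped) {
      perm <- sample.int(n)
      k <- round(fraction * n)
      return(list(train = sort(perm[seq_len(k)]),
                  test = sort(perm[-seq_len(k)])))
    }
    subs <- unique(subject_ids)
    perm <- sample(subs)
    sizes <- vapply(perm, function(s) sum(subject_ids == s), integer(1))
    cum <- cumsum(sizes)
    k <- which.min(abs(cum - fraction * n))
    train_subs <- perm[seq_len(k)]
    list(train = which(subject_ids %in% train_subs),
         test = which(!subject_ids %in% train_subs))
  })
}

#' Glucose regression metrics
#'
#' Computes MAE, MSE, RMSE (mmol/L scale), MAPE and MARD (percent) and the
#' coefficient of determination R^2. MAPE and MARD share the same formula
#' for positive references and will coincide whenever `y_true > 0`
#' elementwise.
#'
#' @param y_true Reference BGL values (mmol/L), all non-zero, length >= 2.
#' @param y_pred Predicted BGL values, same length.
#' @return An object of class `metrics_report`: list with `mae`, `mse`,
#'   `rmse`, `mape`, `r2`, `mard`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_input("`y_true` and `y_pred` must have equal length")
  }
  n <- length(y_true)
  if (n < 2L) stop_input("need at least 2 observations")
  z <- which(y_true == 0)
  if (length(z) > 0L) {
    stop_input("zero reference value at index ", z[1],
               ": percentage errors undefined")
  }
  err <- y_true - y_pred
  mae <- mean(abs(err))
  mse <- mean(err^2)
  rmse <- sqrt(mse)
  mape <- 100 * mean(abs(y_pred - y_true) / abs(y_true))
  mard <- 100 * mean(abs(y_pred - y_true) / y_true)
  sstot <- sum((y_true - mean(y_true))^2)
  ssres <- sum(err^2)
  if (sstot == 0) {
    if (ssres == 0) {
      r2 <- 1
    } else {
      stop_input("degenerate variance: constant `y_true` with imperfect ",
                 "predictions leaves R^2 undefined")
    }
  } else {
    r2 <- 1 - ssres / sstot
  }
  structure(list(mae = mae, mse = mse, rmse = rmse, mape = mape, r2 = r2,
                 mard = mard, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "BGL regression metrics (n=%d)\n  MAE  %.4f mmol/L   MSE  %.4f   RMSE %.4f mmol/L\n  MAPE %.3f %%   MARD %.3f %%   R^2  %.4f\n",
    x$n, x$mae, x$mse, x$rmse, x$mape, x$mard, x$r2))
  invisible(x)
}

#' Categorise a glucose value
#'
#' Maps a BGL (mmol/L) onto the three clinical bands — C1 "Normal"
#' (3.9-6.1), C2 "Prediabetic" (6.2-7.8), C3 "Diabetic" (7.9-11). The
#' printed bands leave gaps, so classification uses half-open midpoint
#' boundaries (\[3.9, 6.15), \[6.15, 7.85), \[7.85, Inf)) to stay total and
#' monotone; values below 3.9 keep label C1 with an out-of-band
#' "hypoglycemic-range" flag, values above 11 keep C3 with an
#' "above-diabetic-band" flag.
#'
#' @param bgl Positive glucose value in mmol/L.
#' @return List with `label` (C1/C2/C3), `level` (Normal / Prediabetic /
#'   Diabetic), `range` (printed band, mmol/L) and `flag` (character,
#'   possibly empty).
#' @export
categorize_glucose <- function(bgl) {
  if (!is.numeric(bgl) || length(bgl) != 1L || !is.finite(bgl) || bgl <= 0) {
    stop_input("`bgl` must be a single positive value")
  }
  flag <- character(0)
  if (bgl < 3.9) flag <- "hypoglycemic-range"
  if (bgl > 11) flag <- "above-diabetic-band"
  if (bgl < 6.15) {
    list(label = "C1", level = "Normal", range = c(3.9, 6.1), flag = flag)
  } else if (bgl < 7.85) {
    list(label = "C2", level = "Prediabetic", range = c(6.2, 7.8),
         flag = flag)
  } else {
    list(label = "C3", level = "Diabetic", range = c(7.9, 11), flag = flag)
  }
}

#' Relative improvement between two error values
#'
#' `100 * (base - enhanced) / base`, the percentage used when reporting
#' ablation gains (e.g. RMSE 0.085 -> 0.062 is a 27.06% improvement).
#'
#' @param base Baseline error value.
#' @param enhanced Enhanced-model error value.
#' @return Improvement in percent.
#' @export
improvement_pct <- function(base, enhanced) 100 * (base - enhanced) / base

#' Ablation study: baseline vs self-attention variant
#'
#' For each seed, splits the data (grouped by subject), trains the model
#' with attention disabled and enabled on the identical split, and reports
#' per-seed and mean +/- SD test metrics together with the relative
#' improvements for RMSE, MAE, MSE and MAPE. Results can be mirrored to
#' CSV + JSON under `out_dir`.
#'
#' @param x Segment array as produced by [segments_to_array()].
#' @param fv Feature matrix (32 x n) or `NULL`.
#' @param y Reference BGL vector (mmol/L).
#' @param subject_ids Subject identifier per sample (for grouped splits).
#' @param seeds Integer vector of at least 3 seeds.
#' @param config A [model_config()]; its `use_attention` field is
#'   overridden per variant.
#' @param tc A [train_config()]; its seed is overridden per ablation seed.
#' @param model Which architecture to ablate, `"dscnet"` or `"cnn"`.
#' @param out_dir Optional directory for `ablation.csv` / `ablation.json`.
#' @return List with `per_seed` (data.frame), `summary` (mean and SD per
#'   metric and variant) and `delta_pct` (named improvements).
#' @export
run_ablation <- function(x, fv, y, subject_ids, seeds, config, tc,
                         model = c("dscnet", "cnn"), out_dir = NULL) {
  model <- match.arg(model)
  if (length(seeds) < 3L) stop_input("need at least 3 seeds")
  rows <- list()
  for (s in seeds) {
    sp <- split_train_test(subject_ids, fraction = tc$split_fraction,
                           seed = s)
    for (attn in c(FALSE, TRUE)) {
      cfg <- config
      cfg$use_attention <- attn
      tcs <- tc
      tcs$seed <- s
      built <- if (model == "dscnet") {
        build_dscnet(cfg, input_len = dim(x)[2], seed = s)
      } else {
        build_cnn_baseline(cfg, attention = attn, input_len = dim(x)[2],
                           seed = s)
      }
      fit <- train_model(built, x[, , sp$train, drop = FALSE], y[sp$train],
                         fv = if (is.null(fv)) NULL else
                           fv[, sp$train, drop = FALSE],
                         tc = tcs)
      pred <- predict_bgl(fit$model, x[, , sp$test, drop = FALSE],
                          fv = if (is.null(fv)) NULL else
                            fv[, sp$test, drop = FALSE])
      m <- compute_metrics(y[sp$test], pred)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, attention = attn, mae = m$mae, mse = m$mse, rmse = m$rmse,
        mape = m$mape, r2 = m$r2, mard = m$mard, n = m$n)
    }
  }
  per_seed <- do.call(rbind, rows)
  metric_cols <- c("mae", "mse", "rmse", "mape", "r2", "mard")
  agg <- function(attn, f) {
    vapply(metric_cols,
           function(mc) f(per_seed[per_seed$attention == attn, mc]),
           numeric(1))
  }
  summary <- data.frame(
    metric = metric_cols,
    base_mean = agg(FALSE, mean), base_sd = agg(FALSE, stats::sd),
    attn_mean = agg(TRUE, mean), attn_sd = agg(TRUE, stats::sd),
    row.names = NULL)
  err_cols <- c("rmse", "mae", "mse", "mape")
  delta <- vapply(err_cols, function(mc) {
    improvement_pct(mean(per_seed[!per_seed$attention, mc]),
                    mean(per_seed[per_seed$attention, mc]))
  }, numeric(1))
  out <- list(per_seed = per_seed, summary = summary, delta_pct = delta)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(per_seed, file.path(out_dir, "ablation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = summary, delta_pct = as.list(delta)),
                         file.path(out_dir, "ablation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Bland-Altman agreement report
#'
#' Mean bias, SD of the paired differences and the 1.96-SD limits of
#' agreement, plus the paired series for plotting. Optionally written to
#' CSV.
#'
#' @param y_true Reference values (mmol/L).
#' @param y_pred Device / model estimates (mmol/L), same length >= 2.
#' @param out_path Optional CSV path for the paired series.
#' @return List with `bias`, `sd_diff`, `loa_lower`, `loa_upper` and
#'   `data` (data.frame with `mean` and `difference` columns).
#' @export
agreement_report <- function(y_true, y_pred, out_path = NULL) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L) {
    stop_input("need paired vectors of equal length >= 2")
  }
  d <- y_pred - y_true
  bias <- mean(d)
  sdd <- stats::sd(d)
  res <- list(bias = bias, sd_diff = sdd,
              loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd,
              data = data.frame(mean = (y_true + y_pred) / 2,
                                difference = d))
  if (!is.null(out_path)) {
    utils::write.csv(cbind(res$data, y_true = y_true, y_pred = y_pred),
                     out_path, row.names = FALSE)
  }
  res
}
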