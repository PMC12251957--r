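# Experiment harnesses: lambda sensitivity sweep, band-combination ablation,
# architecture ablation, GNDVI functional comparison, and k-fold
# benchmarking. Each harness trains/evaluates under identical configuration
# across conditions and returns a reproducible report (config + seed
# embedded).

experiment_report <- function(kind, table, best_condition, config, seed) {
  structure(list(experiment_kind = kind, table = table,
                 best_condition = best_condition, config = config,
                 seed = seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<%s experiment: %d condition(s); best: %s>\n",
              x$experiment_kind, nrow(x$table),
              paste(x$best_condition, collapse = ", ")))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# Shared helper: train on a list of (x, y) samples and score the validation
# partition with the full metrics report.
train_and_score <- function(xs, ys, model_config, train_config) {
  fit <- fusenet(xs, ys, config = model_config, train_config = train_config)
  preds <- predict(fit, fit$val_data$x)
  reps <- mapply(function(p, t) metrics_report(t, p), preds, fit$val_data$y,
                 SIMPLIFY = FALSE)
  agg <- lapply(stats::setNames(nm = names(reps[[1]])), function(k)
    mean(vapply(reps, function(r) as.numeric(r[[k]]), 0), na.rm = TRUE))
  list(fit = fit, metrics = agg)
}

pairs_inputs <- function(pairs, input_mode, lambda) {
  lapply(pairs, function(p) {
    img <- if (input_mode == "grgb")
      build_grgb(p$rgb, grgb_params(lambda)) else p$rgb
    x <- unclass(img)
    attributes(x) <- list(dim = dim(img))
    x
  })
}

pairs_targets <- function(pairs, combination) {
  lapply(pairs, function(p) band_slice(p$cube, combination))
}

#' Lambda sensitivity sweep
#'
#' For each adjustment coefficient, builds G-RGB inputs, trains the model
#' under identical configuration, and scores MSE/PSNR/SSIM on the
#' validation partition. Best condition: lowest MSE, ties broken by higher
#' SSIM.
#'
#' @param pairs list of [dataset_pair()] objects.
#' @param lambdas coefficients to sweep (default 0.1 to 1.0 by 0.1).
#' @param model_config a [fusenet_config()].
#' @param train_config a [fusenet_train_config()].
#' @param combination 0-based target band triple.
#' @return an `experiment_report` with one row per lambda.
#' @export
lambda_sweep <- function(pairs, lambdas = seq(0.1, 1.0, by = 0.1),
                         model_config = fusenet_config("tiny"),
                         train_config = fusenet_train_config("tiny"),
                         combination = c(70L, 91L, 108L)) {
  assert_that(length(lambdas) >= 1L, "no lambda values supplied",
              class = "pseudonir_config_error")
  ys <- pairs_targets(pairs, combination)
  rows <- lapply(lambdas, function(lam) {
    xs <- pairs_inputs(pairs, "grgb", lam)
    sc <- train_and_score(xs, ys, model_config, train_config)$metrics
    data.frame(lambda = lam, mse = sc$mse, psnr_db = sc$psnr_db,
               ssim = sc$ssim)
  })
  tab <- do.call(rbind, rows)
  best <- tab[order(tab$mse, -tab$ssim), ][1, "lambda"]
  experiment_report("lambda_sweep", tab, c(lambda = best),
                    list(model = model_config, train = train_config,
                         combination = combination),
                    train_config$seed)
}

#' Band-combination ablation
#'
#' Trains and evaluates one model per target band combination under
#' identical configuration, ranking combinations by validation MSE.
#' Combinations must be valid (early, mid, late) triples.
#'
#' @param pairs list of [dataset_pair()] objects.
#' @param combinations list of 0-based band triples.
#' @param model_config,train_config shared configuration.
#' @param input_mode "grgb" or "rgb".
#' @param lambda G-RGB coefficient (input_mode = "grgb").
#' @param scheme a [band_group_scheme()] used to validate combinations.
#' @return an `experiment_report` ranked by MSE.
#' @export
band_combination_experiment <- function(pairs, combinations,
                                        model_config = fusenet_config("tiny"),
                                        train_config =
                                          fusenet_train_config("tiny"),
                                        input_mode = c("grgb", "rgb"),
                                        lambda = 0.5,
                                        scheme = band_group_scheme()) {
  input_mode <- match.arg(input_mode)
  assert_that(length(combinations) >= 1L, "no combinations supplied",
              class = "pseudonir_config_error")
  nb <- dim(pairs[[1]]$cube)[3]
  for (comb in combinations) {
    validate_combination(comb, scheme)
    assert_that(max(comb) <= nb - 1L, "combination exceeds cube band count",
                class = "pseudonir_config_error")
  }
  xs <- pairs_inputs(pairs, input_mode, lambda)
  rows <- lapply(combinations, function(comb) {
    sc <- train_and_score(xs, pairs_targets(pairs, comb),
                          model_config, train_config)$metrics
    data.frame(combination = paste(comb, collapse = "-"), mse = sc$mse,
               psnr_db = sc$psnr_db, ssim = sc$ssim, scc = sc$scc)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$mse), ]
  experiment_report("band_combination", tab,
                    c(combination = tab$combination[1]),
                    list(model = model_config, train = train_config,
                         input_mode = input_mode, lambda = lambda),
                    train_config$seed)
}

#' Architecture ablation
#'
#' Builds and trains the four model variants (A: neither module, B:
#' multi-scale only, C: mixer only, Full: both) on the same standard RGB
#' input, reporting MSE/PSNR/SCC/SSIM and parameter counts.
#'
#' @param pairs list of [dataset_pair()] objects.
#' @param variants named list of `c(use_mixer, use_msc)` logical pairs.
#' @param model_config,train_config shared configuration.
#' @param combination target band triple.
#' @return an `experiment_report`, one row per variant.
#' @export
ablation_experiment <- function(pairs,
                                variants = list(A = c(FALSE, FALSE),
                                                B = c(FALSE, TRUE),
                                                C = c(TRUE, FALSE),
                                                Full = c(TRUE, TRUE)),
                                model_config = fusenet_config("tiny"),
                                train_config = fusenet_train_config("tiny"),
                                combination = c(70L, 91L, 108L)) {
  assert_that(length(variants) >= 1L, "no variants supplied",
              class = "pseudonir_config_error")
  xs <- pairs_inputs(pairs, "rgb", 0)  # same standard RGB input for all
  ys <- pairs_targets(pairs, combination)
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    cfg <- model_config
    cfg$use_mixer <- v[1]; cfg$use_msc <- v[2]
    sc <- train_and_score(xs, ys, cfg, train_config)
    data.frame(variant = nm, use_mixer = v[1], use_msc = v[2],
               n_parameters = n_parameters(sc$fit$layers),
               mse = sc$metrics$mse, psnr_db = sc$metrics$psnr_db,
               scc = sc$metrics$scc, ssim = sc$metrics$ssim)
  })
  tab <- do.call(rbind, rows)
  best <- tab$variant[which.min(tab$mse)]
  experiment_report("architecture_ablation", tab, c(variant = best),
                    list(model = model_config, train = train_config,
                         combination = combination),
                    train_config$seed)
}

#' GNDVI functional comparison of two trained predictors
#'
#' For each evaluation pair, computes the ground-truth GNDVI map from the
#' true NIR band (by default the middle band of the combination) against the
#' green channel, and the predicted GNDVI from each model's predicted NIR;
#' reports per-sample RMSE, Pearson correlation and histogram similarity per
#' input mode, plus their means.
#'
#' @param pairs evaluation [dataset_pair()]s with true cubes.
#' @param model_rgb model trained on plain RGB inputs.
#' @param model_grgb model trained on G-RGB inputs.
#' @param lambda G-RGB coefficient used for `model_grgb` inputs.
#' @param combination band triple the models predict.
#' @param nir_band_pos which predicted band defines GNDVI (default 2, the
#'   mid-NIR band).
#' @return an `experiment_report`; table has one row per sample x mode.
#' @export
gndvi_functional_comparison <- function(pairs, model_rgb, model_grgb,
                                        lambda = 0.5,
                                        combination = c(70L, 91L, 108L),
                                        nir_band_pos = 2L) {
  assert_that(all(vapply(pairs, function(p) !is.null(p$cube), TRUE)),
              "every evaluation pair needs a true cube")
  rows <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    green <- unclass(p$rgb)[, , 2]
    truth_nir <- band_slice(p$cube, combination[nir_band_pos])[, , 1]
    truth_map <- compute_index(truth_nir, green, "gndvi")
    for (mode in c("rgb", "grgb")) {
      x <- pairs_inputs(list(p), mode, lambda)[[1]]
      model <- if (mode == "rgb") model_rgb else model_grgb
      pred_nir <- predict(model, x)[, , nir_band_pos]
      pred_map <- compute_index(pred_nir, green, "gndvi")
      fid <- evaluate_gndvi_fidelity(pred_map, truth_map)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = p$identifier, input_mode = mode, rmse = fid$rmse,
        pearson = fid$pearson,
        histogram_similarity = fid$histogram_similarity)
    }
  }
  tab <- do.call(rbind, rows)
  means <- stats::aggregate(tab[c("rmse", "pearson",
                                  "histogram_similarity")],
                            by = list(input_mode = tab$input_mode),
                            function(v) mean(v, na.rm = TRUE))
  best <- means$input_mode[which.min(means$rmse)]
  rep <- experiment_report("gndvi_functional", tab, c(input_mode = best),
                           list(lambda = lambda, combination = combination,
                                nir_band_pos = nir_band_pos), NA_integer_)
  rep$means <- means
  rep
}

#' K-fold benchmark
#'
#' Splits the pairs into k folds (stratified when scene labels are present),
#' trains on k-1 folds, scores the held-out fold, and aggregates each metric
#' as mean and standard deviation across folds.
#'
#' @param pairs list of [dataset_pair()] objects.
#' @param k number of folds.
#' @param model_config,train_config shared configuration.
#' @param input_mode "grgb" or "rgb".
#' @param lambda G-RGB coefficient.
#' @param combination target band triple.
#' @param seed fold-assignment seed.
#' @return an `experiment_report`; `$table` has one row per fold,
#'   `$aggregate` the mean +/- sd per metric.
#' @export
kfold_benchmark <- function(pairs, k = 5L,
                            model_config = fusenet_config("tiny"),
                            train_config = fusenet_train_config("tiny"),
                            input_mode = c("grgb", "rgb"), lambda = 0.5,
                            combination = c(70L, 91L, 108L), seed = 1L) {
  input_mode <- match.arg(input_mode)
  folds <- split_dataset(pairs, mode = "kfold", k = k, seed = seed)
  xs <- pairs_inputs(pairs, input_mode, lambda)
  ys <- pairs_targets(pairs, combination)
  ids <- vapply(pairs, function(p) p$identifier, character(1))
  rows <- lapply(seq_len(k), function(f) {
    test <- which(folds[ids] == f)
    train <- setdiff(seq_along(pairs), test)
    fit <- fusenet(xs[train], ys[train], config = model_config,
                   train_config = train_config)
    preds <- predict(fit, xs[test])
    reps <- mapply(function(p, t) metrics_report(t, p), preds, ys[test],
                   SIMPLIFY = FALSE)
    data.frame(fold = f,
               mse = mean(vapply(reps, function(r) r$mse, 0)),
               psnr_db = mean(vapply(reps, function(r) r$psnr_db, 0)),
               scc = mean(vapply(reps, function(r) r$scc, 0), na.rm = TRUE),
               ssim = mean(vapply(reps, function(r) r$ssim, 0)))
  })
  tab <- do.call(rbind, rows)
  agg <- data.frame(
    metric = c("mse", "psnr_db", "scc", "ssim"),
    mean = vapply(c("mse", "psnr_db", "scc", "ssim"),
                  function(m) mean(tab[[m]]), 0),
    sd = vapply(c("mse", "psnr_db", "scc", "ssim"),
                function(m) stats::sd(tab[[m]]), 0))
  rownames(agg) <- NULL
  rep <- experiment_report("kfold_benchmark", tab,
                           c(fold = tab$fold[which.min(tab$mse)]),
                           list(model = model_config, train = train_config,
                                input_mode = input_mode, lambda = lambda,
                                combination = combination, k = k), seed)
  rep$aggregate <- agg
  rep
}
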