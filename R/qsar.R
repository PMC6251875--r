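# QSAR machinery: response transforms, z-score normalization, small multiple
# linear regression models with leave-one-out Q2, exhaustive subset search,
# the seven published laccase models as fixed predictors, and prediction with
# trend validation.

#' Michaelis constant to pK_m
#'
#' K_m values in micromolar are converted to molar units and expressed as the
#' negative base-10 logarithm: `pK_m = -log10(K_m * 1e-6)`.
#'
#' @param km Michaelis constant(s), micromolar.
#' @return pK_m value(s).
#' @examples
#' km_to_pkm(100)  # 4
#' @export
km_to_pkm <- function(km) {
  if (any(km <= 0)) stop("K_m must be positive", call. = FALSE)
  -log10(km * 1e-6)
}

#' Inverse of [km_to_pkm()]
#' @param pkm pK_m value(s).
#' @return K_m in micromolar.
#' @export
pkm_to_km <- function(pkm) 10^(-pkm) * 1e6

#' Relative activity to log10(activity)
#' @param a relative activity value(s), > 0.
#' @return base-10 logarithm.
#' @export
activity_to_log <- function(a) {
  if (any(a <= 0)) stop("relative activity must be positive", call. = FALSE)
  log10(a)
}

#' Z-score normalization of descriptor columns
#'
#' Normalizes the given columns to zero mean / unit standard deviation and
#' stores the training parameters so external data can be transformed with
#' the same reference population (pass the returned parameters as `params`).
#'
#' @param data a data frame.
#' @param cols character vector of columns to normalize; default: all numeric
#'   columns except `except`.
#' @param except columns never normalized (ids, responses).
#' @param params optional parameter tibble from a previous call (`column`,
#'   `mean`, `sd`) — when supplied, those parameters are applied instead of
#'   being estimated.
#' @return the normalized tibble with attribute `norm_params`.
#' @export
normalize_descriptors <- function(data, cols = NULL, except = character(),
                                  params = NULL) {
  data <- tibble::as_tibble(data)
  if (!is.null(params)) {
    missing <- setdiff(params$column, names(data))
    if (length(missing)) {
      stop("data lacks columns required by the normalization parameters: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (r in seq_len(nrow(params))) {
      cl <- params$column[r]
      data[[cl]] <- (data[[cl]] - params$mean[r]) / params$sd[r]
    }
    attr(data, "norm_params") <- params
    return(data)
  }
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
    cols <- setdiff(cols, except)
  }
  sds <- vapply(data[cols], stats::sd, numeric(1))
  if (any(sds == 0 | is.na(sds))) {
    bad <- cols[sds == 0 | is.na(sds)]
    stop("constant (degenerate) descriptor column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mus <- vapply(data[cols], mean, numeric(1))
  for (cl in cols) data[[cl]] <- (data[[cl]] - mus[cl]) / sds[cl]
  attr(data, "norm_params") <- tibble::tibble(column = cols,
                                              mean = unname(mus),
                                              sd = unname(sds))
  data
}

#' Extract normalization parameters
#' @param data result of [normalize_descriptors()].
#' @return tibble with `column`, `mean`, `sd`.
#' @export
norm_params <- function(data) attr(data, "norm_params")

bt <- function(x) paste0("`", x, "`")

new_qsar_model <- function(intercept, coefficients, normalization = NULL,
                           metrics = list(), provenance = "fitted",
                           response = "response", fit = NULL) {
  structure(
    list(intercept = intercept, coefficients = coefficients,
         normalization = normalization, metrics = metrics,
         provenance = provenance, response = response, fit = fit),
    class = "qsar_model"
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  terms <- paste(sprintf("%+.3g %s", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat("<qsar_model> [", x$provenance, "] ", x$response, " = ",
      format(x$intercept, digits = 3), " ", terms, "\n", sep = "")
  m <- x$metrics
  if (length(m)) {
    cat(sprintf("  R2 = %.3f  Q2 = %s  SE = %s  n = %s\n",
                m$r_squared %||% NA,
                ifelse(is.null(m$q_squared) || is.na(m$q_squared), "NA",
                       sprintf("%.3f", m$q_squared)),
                ifelse(is.null(m$std_error), "NA",
                       sprintf("%.3f", m$std_error)),
                m$n %||% "NA"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a small multiple-linear-regression QSAR model
#'
#' Ordinary least squares on at most `max_k` descriptors (default 3,
#' mirroring the published model size). Reports R-squared, residual standard
#' error, the overall F-test p-value and (optionally) the leave-one-out
#' Q-squared.
#'
#' @param data data frame with the response and descriptor columns.
#' @param response response column name (e.g. `"pkm"` or `"log_activity"`).
#' @param descriptors character vector of descriptor column names.
#' @param max_k maximum number of descriptors allowed (default 3).
#' @param normalize z-score the descriptors before fitting and store the
#'   parameters in the model (default `FALSE`).
#' @param compute_q2 also compute the exhaustive leave-one-out Q2.
#' @return a `qsar_model`.
#' @export
fit_mlr <- function(data, response, descriptors, max_k = 3,
                    normalize = FALSE, compute_q2 = TRUE) {
  data <- tibble::as_tibble(data)
  if (length(descriptors) > max_k) {
    stop("more than max_k = ", max_k, " descriptors requested", call. = FALSE)
  }
  missing <- setdiff(c(response, descriptors), names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  if (n <= length(descriptors) + 1) {
    stop("need n > number of descriptors + 1 observations", call. = FALSE)
  }
  norm <- NULL
  if (normalize) {
    data_n <- normalize_descriptors(data, cols = descriptors)
    norm <- norm_params(data_n)
    data <- data_n
  }
  X <- as.matrix(data[descriptors])
  if (qr(cbind(1, X))$rank < length(descriptors) + 1) {
    stop("rank-deficient (collinear) design matrix", call. = FALSE)
  }
  fml <- stats::as.formula(paste(bt(response), "~",
                                 paste(bt(descriptors), collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  sm <- summary(fit)
  pval <- if (length(descriptors) > 0 && !is.null(sm$fstatistic)) {
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  } else NA_real_
  coefs <- stats::coef(fit)
  names(coefs) <- gsub("`", "", names(coefs))
  q2 <- if (compute_q2) loo_q2(data, response, descriptors) else NA_real_
  new_qsar_model(
    intercept = unname(coefs["(Intercept)"]),
    coefficients = coefs[setdiff(names(coefs), "(Intercept)")],
    normalization = norm,
    metrics = list(r_squared = sm$r.squared, q_squared = q2,
                   std_error = sm$sigma, n = n, p_value = unname(pval)),
    provenance = "fitted",
    response = response,
    fit = fit
  )
}

#' Leave-one-out cross-validated Q-squared
#'
#' `Q2 = 1 - PRESS / SS_tot`, each observation predicted by the model refit
#' without it — computed exactly over all n leave-one-out folds via the hat
#' matrix identity `e_(i) = e_i / (1 - h_ii)`.
#'
#' @inheritParams fit_mlr
#' @return Q2 (scalar; can be negative for models worse than the mean).
#' @export
loo_q2 <- function(data, response, descriptors) {
  data <- tibble::as_tibble(data)
  y <- data[[response]]
  X <- cbind(`(Intercept)` = 1, as.matrix(data[descriptors]))
  fit <- stats::lm.fit(X, y)
  h <- stats::hat(X, intercept = FALSE)
  press <- sum((fit$residuals / pmax(1 - h, 1e-12))^2)
  sstot <- sum((y - mean(y))^2)
  1 - press / sstot
}

#' Exhaustive best-subset QSAR search
#'
#' Fits every descriptor subset of size 1..`max_k` and ranks the models by
#' the chosen criterion (in-sample R2 or leave-one-out Q2). Ties are broken
#' by fewer descriptors, then lexicographic descriptor names.
#'
#' @param data data frame of response + candidate descriptors.
#' @param response response column name.
#' @param candidates candidate descriptor columns (default: all numeric
#'   columns except the response and `exclude`); at most 25.
#' @param max_k largest subset size (default 3).
#' @param criterion `"q2"` (default) or `"r2"`.
#' @param exclude columns never considered (ids, external responses).
#' @return a tibble ranked best-first: `rank`, `descriptors` (collapsed
#'   names), `k`, `r_squared`, `q_squared`, `std_error`, `p_value`, `model`
#'   (list-column of `qsar_model`s).
#' @export
subset_search <- function(data, response, candidates = NULL, max_k = 3,
                          criterion = c("q2", "r2"), exclude = character()) {
  criterion <- match.arg(criterion)
  data <- tibble::as_tibble(data)
  if (is.null(candidates)) {
    candidates <- names(data)[vapply(data, is.numeric, logical(1))]
    candidates <- setdiff(candidates, c(response, exclude))
  }
  if (length(candidates) > 25) {
    stop("more than 25 candidate descriptors (", length(candidates),
         "); exhaustive search would be too large - prefilter the table",
         call. = FALSE)
  }
  subsets <- unlist(lapply(seq_len(min(max_k, length(candidates))),
                           function(k) {
                             utils::combn(sort(candidates), k,
                                          simplify = FALSE)
                           }), recursive = FALSE)
  models <- purrr::map(subsets, function(d) {
    tryCatch(fit_mlr(data, response, d, max_k = max_k, compute_q2 = TRUE),
             error = function(e) NULL)
  })
  keep <- !vapply(models, is.null, logical(1))
  subsets <- subsets[keep]; models <- models[keep]
  res <- tibble::tibble(
    descriptors = vapply(subsets, paste, character(1), collapse = " + "),
    k = lengths(subsets),
    r_squared = vapply(models, function(m) m$metrics$r_squared, numeric(1)),
    q_squared = vapply(models, function(m) m$metrics$q_squared, numeric(1)),
    std_error = vapply(models, function(m) m$metrics$std_error, numeric(1)),
    p_value = vapply(models, function(m) m$metrics$p_value, numeric(1)),
    model = models
  )
  score <- if (criterion == "q2") res$q_squared else res$r_squared
  ord <- order(-score, res$k, res$descriptors)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  dplyr::relocate(res, "rank")
}

published_model_table <- list(
  list(response = "log_activity", intercept = 1.38,
       coefficients = c("QPlogPo/w" = 1.36, "QPlogS" = 0.88,
                        "ESP_max" = -0.97),
       metrics = list(r_squared = 0.76, q_squared = 0.57, std_error = 0.21,
                      n = 12)),
  list(response = "log_activity", intercept = 3.6,
       coefficients = c("FISA" = -1.89, "glob" = -2.64, "QPlogS" = 1.41),
       metrics = list(r_squared = 0.74, q_squared = 0.50, std_error = 0.30,
                      n = 15)),
  list(response = "log_activity", intercept = 1.98,
       coefficients = c("PISA" = 0.94, "EA" = 1.00, "ESP_max" = -1.23),
       metrics = list(r_squared = 0.80, q_squared = 0.59, std_error = 0.20,
                      n = 12)),
  list(response = "log_activity", intercept = -0.44,
       coefficients = c("QPlogPo/w" = 1.72, "QPlogS" = 1.87,
                        "Vol/SASA" = 1.91),
       metrics = list(r_squared = 0.82, q_squared = 0.67, std_error = 0.24,
                      n = 15)),
  list(response = "pkm", intercept = 4.43,
       coefficients = c("IP" = -2.93),
       metrics = list(r_squared = 0.62, q_squared = 0.53, std_error = 0.60,
                      n = 22)),
  list(response = "pkm", intercept = 2.69,
       coefficients = c("accptHB" = 1.99, "IP" = -2.57,
                        "E_Solv_PBF" = 1.51),
       metrics = list(r_squared = 0.77, q_squared = 0.66, std_error = 0.49,
                      n = 22)),
  list(response = "pkm", intercept = 3.04,
       coefficients = c("FISA" = -1.14, "E_o_expt" = -1.79,
                        "Vol/SASA" = 3.98),
       metrics = list(r_squared = 0.74, q_squared = 0.60, std_error = 0.53,
                      n = 23))
)

#' The seven published laccase QSAR models
#'
#' Returns one of the seven published models as a fixed predictor with its
#' printed intercept and coefficients. Models 1-4 predict log(relative
#' activity) of the TvL phenol dataset; models 5-7 predict pK_m of the CuL
#' dataset. All seven act on *normalized* descriptors, so prediction requires
#' a user-declared normalization reference set (see [predict.qsar_model()]);
#' outputs are trend-level, not absolute.
#'
#' @param id model number, 1-7.
#' @return a `qsar_model` with provenance `"published model <id>"`; reported
#'   fit statistics are stored in `metrics`.
#' @examples
#' published_model(5)  # pK_m = 4.43 - 2.93 IP(eV)
#' @export
published_model <- function(id) {
  if (!(length(id) == 1 && id %in% 1:7)) {
    stop("published model id must be 1..7", call. = FALSE)
  }
  spec <- published_model_table[[id]]
  m <- new_qsar_model(
    intercept = spec$intercept,
    coefficients = spec$coefficients,
    normalization = "required",
    metrics = spec$metrics,
    provenance = paste("published model", id),
    response = spec$response
  )
  m$normalized <- TRUE
  m
}

#' Predict from a QSAR model
#'
#' `y-hat = intercept + sum(beta * z(x))`. For normalized models the
#' descriptor columns of `newdata` are z-scored with the model's stored
#' parameters or, for the published models, with parameters estimated from a
#' user-supplied `norm_ref` reference table. When `newdata` contains the
#' model's response column, trend statistics (R2 of predicted vs observed and
#' Spearman rank correlation) are attached as attribute `trend`.
#'
#' @param object a `qsar_model`.
#' @param newdata data frame with the model's descriptor columns.
#' @param norm_ref reference data frame (or parameter tibble with `column`,
#'   `mean`, `sd`) defining the normalization population for normalized
#'   models whose parameters are not stored.
#' @param ... unused.
#' @return `newdata` with an added `.pred` column; attribute `trend` when the
#'   observed response is present.
#' @export
predict.qsar_model <- function(object, newdata, norm_ref = NULL, ...) {
  newdata <- tibble::as_tibble(newdata)
  needed <- names(object$coefficients)
  missing <- setdiff(needed, names(newdata))
  if (length(missing)) {
    stop("newdata lacks model descriptor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[needed])
  is_norm <- isTRUE(object$normalized) ||
    (is.data.frame(object$normalization))
  if (is_norm) {
    params <- if (is.data.frame(object$normalization)) {
      object$normalization
    } else if (is.data.frame(norm_ref) && all(c("column", "mean", "sd") %in%
                                              names(norm_ref))) {
      norm_ref
    } else if (is.data.frame(norm_ref)) {
      ref_missing <- setdiff(needed, names(norm_ref))
      if (length(ref_missing)) {
        stop("norm_ref lacks descriptor(s): ",
             paste(ref_missing, collapse = ", "), call. = FALSE)
      }
      tibble::tibble(
        column = needed,
        mean = vapply(norm_ref[needed], mean, numeric(1)),
        sd = vapply(norm_ref[needed], stats::sd, numeric(1))
      )
    } else {
      stop("model uses normalized descriptors: supply norm_ref ",
           "(a reference table or normalization parameters)", call. = FALSE)
    }
    for (d in needed) {
      r <- params[params$column == d, ]
      if (nrow(r) == 0) {
        stop("no normalization parameters for descriptor ", d, call. = FALSE)
      }
      X[, d] <- (X[, d] - r$mean) / r$sd
    }
  }
  pred <- drop(object$intercept + X %*% object$coefficients)
  out <- newdata
  out$.pred <- pred
  if (object$response %in% names(newdata)) {
    obs <- newdata[[object$response]]
    r <- stats::cor(pred, obs)
    attr(out, "trend") <- tibble::tibble(
      r_squared = r^2,
      spearman_rho = stats::cor(pred, obs, method = "spearman"),
      n = length(obs)
    )
  }
  out
}

#' Trend statistics of a prediction
#' @param predictions result of [predict.qsar_model()] on data with the
#'   observed response.
#' @return tibble with `r_squared`, `spearman_rho`, `n` (or `NULL`).
#' @export
trend_stats <- function(predictions) attr(predictions, "trend")

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a QSAR model
#' @param x a `qsar_model`.
#' @param ... unused.
#' @return tibble with `term` and `estimate` (intercept first).
#' @export
tidy.qsar_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' One-row model summary of a QSAR model
#' @param x a `qsar_model`.
#' @param ... unused.
#' @return tibble with `r_squared`, `q_squared`, `std_error`, `n`, `p_value`,
#'   `provenance`.
#' @export
glance.qsar_model <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    r_squared = m$r_squared %||% NA_real_,
    q_squared = m$q_squared %||% NA_real_,
    std_error = m$std_error %||% NA_real_,
    n = m$n %||% NA_integer_,
    p_value = m$p_value %||% NA_real_,
    provenance = x$provenance
  )
}

#' Serialize a QSAR model to JSON
#' @param model a `qsar_model`.
#' @param path output path.
#' @param data_hash optional provenance hash of the training table.
#' @return `path`, invisibly.
#' @export
write_qsar_model <- function(model, path, data_hash = NULL) {
  obj <- list(
    response = model$response,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    normalization = if (is.data.frame(model$normalization)) {
      model$normalization
    } else as.character(model$normalization %||% "none"),
    metrics = model$metrics[!vapply(model$metrics, is.null, logical(1))],
    provenance = model$provenance,
    data_hash = data_hash
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a QSAR model from JSON written by [write_qsar_model()]
#' @param path JSON path.
#' @return a `qsar_model`.
#' @export
read_qsar_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- obj$normalization
  if (is.data.frame(norm)) norm <- tibble::as_tibble(norm)
  else if (identical(norm, "none")) norm <- NULL
  m <- new_qsar_model(
    intercept = obj$intercept,
    coefficients = unlist(obj$coefficients),
    normalization = norm,
    metrics = as.list(obj$metrics),
    provenance = obj$provenance,
    response = obj$response
  )
  if (identical(obj$normalization, "required")) m$normalized <- TRUE
  m
}
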