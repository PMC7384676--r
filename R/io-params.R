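## Parameter archives ---------------------------------------------------------
##
## Fitted objects are persisted as versioned JSON so runs are portable and
## diffable.  Matrices are stored with explicit dimensions; NULL components
## (e.g. the hidden layer of a linear model) are omitted.

ARCHIVE_VERSION <- "1.0"

#' Write and read fitted model archives
#'
#' `write_dme_archive` persists a [train_dme()] fit (network weights,
#' `sigma`, feature standardizer, split, training history);
#' `read_dme_archive` restores it to a `dme_fit` usable by
#' [score_variants()].  `write_mutation_model` / `read_mutation_model` do
#' the same for [mutation_model_params()].
#'
#' @param fit A `dme_fit`.
#' @param path Output (input) JSON path.
#' @return The writers return `path` invisibly; the readers return the
#'   restored object.
#' @export
write_dme_archive <- function(fit, path) {
  p <- fit$params
  payload <- list(
    version = ARCHIVE_VERSION, kind = "dme_fit",
    params = list(
      W_hidden = p$W_hidden, B_hidden = p$B_hidden,
      W_output = p$W_output, b_output = p$b_output,
      sigma = p$sigma, hidden_units = p$hidden_units,
      dropout_rate = p$dropout_rate, feature_names = p$feature_names,
      n_features = p$n_features),
    standardizer = unclass(fit$standardizer),
    split = fit$split,
    best_epoch = fit$best_epoch,
    history = fit$history,
    config = unclass(fit$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_dme_archive
#' @export
read_dme_archive <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$kind, "dme_fit"))
    stop_uneecon("%s is not a dme_fit archive", path)
  p <- j$params
  params <- structure(list(
    W_hidden = if (!is.null(p$W_hidden)) as.matrix(p$W_hidden) else NULL,
    B_hidden = if (!is.null(p$B_hidden)) as.numeric(p$B_hidden) else NULL,
    W_output = as.numeric(p$W_output), b_output = as.numeric(p$b_output),
    sigma = p$sigma, hidden_units = as.integer(p$hidden_units),
    dropout_rate = p$dropout_rate, feature_names = p$feature_names,
    n_features = as.integer(p$n_features)), class = "dme_params")
  stdz <- structure(list(center = as.numeric(j$standardizer$center),
                         scale = as.numeric(j$standardizer$scale),
                         kind = j$standardizer$kind,
                         colnames = j$standardizer$colnames),
                    class = "feature_standardizer")
  cfg <- j$config
  if (!is.null(cfg)) class(cfg) <- "train_config"
  structure(list(params = params, standardizer = stdz,
                 history = j$history, split = lapply(j$split, as.character),
                 best_epoch = j$best_epoch, config = cfg),
            class = "dme_fit")
}

#' @rdname write_dme_archive
#' @param params A `mutation_model_params`.
#' @export
write_mutation_model <- function(params, path) {
  stopifnot(inherits(params, "mutation_model_params"))
  payload <- c(list(version = ARCHIVE_VERSION, kind = "mutation_model"),
               unclass(params))
  payload$alpha3 <- as.list(params$alpha3)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_dme_archive
#' @export
read_mutation_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$kind, "mutation_model"))
    stop_uneecon("%s is not a mutation model archive", path)
  mutation_model_params(
    alpha0 = j$alpha0, alpha1 = j$alpha1, alpha2 = j$alpha2,
    alpha3 = unlist(j$alpha3) %||% stats::setNames(numeric(), character()),
    beta0 = j$beta0 %||% NA_real_, window_bp = j$window_bp,
    provenance = j$provenance %||% list())
}

#' Write and read mutability tables as TSV
#'
#' @param tab A `mutability_table`.
#' @param path TSV path.
#' @return `path` invisibly (writer); the restored table (reader).
#' @export
write_mutability_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutability_table
#' @export
read_mutability_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("context7", "alt", "count_total", "count_observed", "f", "F")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_uneecon("mutability table %s missing column(s): %s", path,
                 paste(miss, collapse = ", "))
  class(tab) <- c("mutability_table", "data.frame")
  tab
}
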