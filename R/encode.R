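# Covariates-at-index -> numeric predictor matrix for the survival tree.
# Binary variables (including one-hot columns of categoricals) use a
# three-state code that makes missingness splittable: 0 = known FALSE,
# 1 = missing, 2 = known TRUE, so a split at 0.5 separates known-FALSE from
# {missing, TRUE} and a split at 1.5 separates {known-FALSE, missing} from
# known-TRUE. Continuous variables are median-imputed. Variables missing for
# at least `drop_threshold` of the cohort are excluded up front.

#' Encode cohort covariates for tree fitting
#'
#' @param x a `stage_cohort` (its covariate columns and declared kinds are
#'   used) or a plain data.frame of covariates.
#' @param spec optional named list of [covariate_spec()] declaring each
#'   column's kind; required when `x` is a plain data.frame with ambiguous
#'   column types, otherwise inferred (`logical` -> binary, `numeric` ->
#'   continuous, `character`/`factor` -> categorical).
#' @param drop_threshold variables with a missing fraction at or above this
#'   value are dropped (default 0.20: imputation is only trusted below 20%
#'   missingness).
#' @return An object of class `encoded_matrix`: list with `values`
#'   (numeric matrix, one row per cohort row), `feature_meta` (data.frame:
#'   `feature`, `source`, `kind` in `{three_state_binary, continuous}`,
#'   `level`, `impute_value`, `role`), `dropped` (data.frame `name`,
#'   `missing_fraction`), and `imputed` (list of imputed row indices per
#'   continuous feature, so known values remain decodable).
#' @examples
#' enc <- encode_features(data.frame(flag = c(FALSE, TRUE, NA, TRUE, FALSE, TRUE)))
#' enc$values[, "flag"] # 0 2 1 2 0 2
#' @export
encode_features <- function(x, spec = NULL, drop_threshold = 0.20) {
  if (inherits(x, "stage_cohort")) {
    if (is.null(spec)) spec <- attr(x, "covariate_spec")
    covdf <- as.data.frame(x)[, names(spec), drop = FALSE]
  } else {
    covdf <- as.data.frame(x)
    if (is.null(spec)) {
      spec <- lapply(names(covdf), function(nm) infer_spec(nm, covdf[[nm]]))
      names(spec) <- names(covdf)
    }
  }
  missing_names <- setdiff(names(covdf), names(spec))
  if (length(missing_names)) {
    stop("no declared kind for variable(s): ",
      paste(missing_names, collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(covdf)
  cols <- list()
  meta <- list()
  imputed <- list()
  dropped <- data.frame(name = character(0), missing_fraction = numeric(0))

  for (nm in names(covdf)) {
    cs <- spec[[nm]]
    val <- covdf[[nm]]
    miss_frac <- mean(is.na(val))
    if (miss_frac >= drop_threshold) {
      dropped <- rbind(dropped, data.frame(name = nm, missing_fraction = miss_frac))
      next
    }
    if (cs$kind == "binary") {
      if (!is.logical(val)) {
        if (all(val %in% c(0, 1, NA))) val <- as.logical(val) else {
          stop("binary variable '", nm, "' is not logical/0-1", call. = FALSE)
        }
      }
      cols[[nm]] <- ifelse(is.na(val), 1, ifelse(val, 2, 0))
      meta[[nm]] <- data.frame(
        feature = nm, source = nm, kind = "three_state_binary",
        level = NA_character_, impute_value = NA_real_, role = cs$role
      )
    } else if (cs$kind == "categorical") {
      levs <- if (!is.null(cs$levels)) cs$levels else sort(unique(stats::na.omit(as.character(val))))
      val <- as.character(val)
      for (lv in levs) {
        fname <- paste0(nm, "=", lv)
        cols[[fname]] <- ifelse(is.na(val), 1, ifelse(val == lv, 2, 0))
        meta[[fname]] <- data.frame(
          feature = fname, source = nm, kind = "three_state_binary",
          level = lv, impute_value = NA_real_, role = cs$role
        )
      }
    } else { # continuous
      obs <- val[!is.na(val)]
      if (length(obs) == 0L) {
        stop("all-missing continuous variable '", nm,
          "' below the drop threshold should be impossible",
          call. = FALSE
        )
      }
      imp <- low_median(obs)
      na_rows <- which(is.na(val))
      val[na_rows] <- imp
      cols[[nm]] <- as.numeric(val)
      imputed[[nm]] <- na_rows
      meta[[nm]] <- data.frame(
        feature = nm, source = nm, kind = "continuous",
        level = NA_character_, impute_value = imp, role = cs$role
      )
    }
  }
  values <- if (length(cols)) {
    matrix(unlist(cols, use.names = FALSE),
      nrow = n,
      dimnames = list(NULL, names(cols))
    )
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  feature_meta <- if (length(meta)) {
    do.call(rbind, meta)
  } else {
    data.frame(
      feature = character(0), source = character(0), kind = character(0),
      level = character(0), impute_value = numeric(0), role = character(0)
    )
  }
  rownames(feature_meta) <- NULL
  out <- list(
    values = values, feature_meta = feature_meta, dropped = dropped,
    imputed = imputed, drop_threshold = drop_threshold
  )
  class(out) <- "encoded_matrix"
  out
}

# lower of the two middle order statistics for even counts of integer-valued
# data (keeps imputed values in the observed support); usual median otherwise
low_median <- function(x) {
  if (all(x %% 1 == 0)) sort(x)[ceiling(length(x) / 2)] else stats::median(x)
}

infer_spec <- function(nm, col) {
  if (is.logical(col)) {
    covariate_spec(nm, "binary", prevalence = 0.5)
  } else if (is.numeric(col)) {
    covariate_spec(nm, "continuous", mean = 0, sd = 1)
  } else {
    levs <- sort(unique(stats::na.omit(as.character(col))))
    covariate_spec(nm, "categorical", levels = levs, probs = rep(1, length(levs)))
  }
}

#' Candidate split thresholds of an encoded feature
#'
#' Three-state columns can only split at 0.5 (known-FALSE vs missing-or-TRUE)
#' or 1.5 (known-TRUE vs FALSE-or-missing); continuous columns split at the
#' midpoints of consecutive distinct attained values.
#'
#' @param encoded an `encoded_matrix`.
#' @param feature feature name.
#' @param rows optional row subset over which to enumerate continuous values.
#' @return numeric vector of thresholds (possibly empty).
#' @export
split_thresholds <- function(encoded, feature, rows = NULL) {
  stopifnot(inherits(encoded, "encoded_matrix"))
  meta <- encoded$feature_meta
  j <- match(feature, meta$feature)
  if (is.na(j)) stop("unknown feature '", feature, "'", call. = FALSE)
  v <- encoded$values[, feature]
  if (!is.null(rows)) v <- v[rows]
  uv <- sort(unique(v))
  if (length(uv) < 2L) return(numeric(0))
  if (meta$kind[j] == "three_state_binary") {
    # legal cut points separating the attained codes
    c(0.5, 1.5)[c(0.5, 1.5) > uv[1] & c(0.5, 1.5) < uv[length(uv)]]
  } else {
    (uv[-length(uv)] + uv[-1]) / 2
  }
}

#' Decode an encoded matrix back to covariate values
#'
#' Inverse of [encode_features()] on known values: three-state codes map back
#' to FALSE/TRUE/NA, one-hot groups back to their level (NA when all columns
#' of the group code missing), and continuous imputed rows are restored to
#' NA using the recorded imputation indices.
#'
#' @param encoded an `encoded_matrix`.
#' @return data.frame of source variables.
#' @export
decode_features <- function(encoded) {
  stopifnot(inherits(encoded, "encoded_matrix"))
  meta <- encoded$feature_meta
  out <- list()
  for (src in unique(meta$source)) {
    rows_m <- meta[meta$source == src, , drop = FALSE]
    if (rows_m$kind[1] == "continuous") {
      v <- encoded$values[, rows_m$feature[1]]
      v[encoded$imputed[[src]]] <- NA
      out[[src]] <- v
    } else if (all(is.na(rows_m$level))) {
      code <- encoded$values[, rows_m$feature[1]]
      out[[src]] <- ifelse(code == 1, NA, code == 2)
    } else {
      sub <- encoded$values[, rows_m$feature, drop = FALSE]
      out[[src]] <- apply(sub, 1, function(r) {
        hit <- which(r == 2)
        if (length(hit) == 1L) rows_m$level[hit] else NA_character_
      })
    }
  }
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf(
    "Encoded matrix: %d rows x %d features (%d three-state, %d continuous); %d variable(s) dropped at >= %.0f%% missing\n",
    nrow(x$values), ncol(x$values),
    sum(x$feature_meta$kind == "three_state_binary"),
    sum(x$feature_meta$kind == "continuous"),
    nrow(x$dropped), 100 * x$drop_threshold
  ))
  invisible(x)
}

#' Write an encoded matrix (values + JSON metadata side-file)
#' @param encoded an `encoded_matrix`; @param path CSV path for the values.
#' @export
write_encoded <- function(encoded, path) {
  stopifnot(inherits(encoded, "encoded_matrix"))
  utils::write.csv(as.data.frame(encoded$values), path, row.names = FALSE)
  jsonlite::write_json(
    list(
      feature_meta = encoded$feature_meta, dropped = encoded$dropped,
      drop_threshold = encoded$drop_threshold
    ),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
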