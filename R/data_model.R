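#' Declare a categorical covariate
#'
#' Fixes the level set and reference level of a covariate explicitly, so
#' that dummy coding and adjusted-odds-ratio tables are reproducible and
#' never depend on the order in which values appear in a file.
#'
#' @param name column name of the covariate.
#' @param levels character vector of allowed levels, in display order.
#' @param reference the reference level; defaults to the first level.
#' @return An object of class `categorical_spec`.
#' @export
categorical_spec <- function(name, levels, reference = levels[1]) {
  levels <- as.character(levels)
  if (anyDuplicated(levels)) stop("duplicate levels in spec for ", name)
  if (!reference %in% levels)
    stop("reference level '", reference, "' not among levels of ", name)
  structure(list(name = name, levels = levels, reference = reference),
            class = "categorical_spec")
}

#' Assemble a unit-level analysis table
#'
#' Wraps a data.frame of unit records (one row per woman) carrying two
#' binary outcomes, a cluster (zone) identifier, optional sampling weights
#' and categorical covariates.  Rows with a missing outcome or cluster id
#' are dropped and counted; missing covariate values are retained (they are
#' excluded later, at design-matrix construction, not here).
#'
#' @param data a data.frame of unit records.
#' @param outcome1,outcome2 names of the two binary outcome columns
#'   (0/1 coded; by convention outcome 1 is adequate antenatal-care contact,
#'   outcome 2 is health-facility delivery).
#' @param cluster name of the cluster-identifier column.
#' @param weight name of the sampling-weight column, or `NULL` for
#'   unit weights.
#' @param schema list of [categorical_spec()] objects declaring the
#'   covariates; values outside a declared level set are a coding error.
#' @return An object of class `bivml_table`: the (filtered) data.frame with
#'   the column mapping, schema and a load report attached as attributes.
#' @export
analysis_table <- function(data, outcome1 = "y1", outcome2 = "y2",
                           cluster = "cluster", weight = NULL,
                           schema = list()) {
  need <- c(outcome1, outcome2, cluster, weight)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  names(schema) <- vapply(schema, `[[`, "", "name")
  miss <- setdiff(names(schema), names(data))
  if (length(miss))
    stop("schema covariate(s) absent from data: ",
         paste(miss, collapse = ", "), call. = FALSE)

  n_in <- nrow(data)
  keep <- !(is.na(data[[outcome1]]) | is.na(data[[outcome2]]) |
              is.na(data[[cluster]]))
  data <- data[keep, , drop = FALSE]

  for (oc in c(outcome1, outcome2)) {
    v <- data[[oc]]
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad))
      stop("non-binary value '", v[bad[1]], "' in outcome '", oc,
           "' at row ", bad[1], call. = FALSE)
    data[[oc]] <- as.integer(v)
  }
  if (!is.null(weight)) {
    if (any(is.na(data[[weight]]) | data[[weight]] < 0))
      stop("weights must be nonnegative and non-missing", call. = FALSE)
  }
  for (sp in schema) {
    v <- data[[sp$name]]
    bad <- which(!is.na(v) & !(as.character(v) %in% sp$levels))
    if (length(bad))
      stop("value '", v[bad[1]], "' in covariate '", sp$name,
           "' at row ", bad[1], " outside declared levels", call. = FALSE)
  }

  structure(data,
            class = c("bivml_table", "data.frame"),
            cols = list(y1 = outcome1, y2 = outcome2,
                        cluster = cluster, weight = weight),
            schema = schema,
            report = list(n_input = n_in, n_kept = nrow(data),
                          drop_count = n_in - nrow(data)))
}

#' Load an analysis table from a CSV file
#'
#' @param path path to a comma-delimited file with a header row.
#' @param schema list of [categorical_spec()] objects.
#' @param outcome1,outcome2,cluster,weight column names, as in
#'   [analysis_table()].
#' @return A `bivml_table`; the attached `report` attribute counts rows
#'   dropped for missing outcome or cluster values.
#' @export
load_table <- function(path, schema = list(), outcome1 = "y1",
                       outcome2 = "y2", cluster = "cluster", weight = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  analysis_table(df, outcome1 = outcome1, outcome2 = outcome2,
                 cluster = cluster, weight = weight, schema = schema)
}

# internal accessors -------------------------------------------------------
.tab_cols <- function(tab) attr(tab, "cols")
.tab_y1 <- function(tab) tab[[.tab_cols(tab)$y1]]
.tab_y2 <- function(tab) tab[[.tab_cols(tab)$y2]]
.tab_cluster <- function(tab) tab[[.tab_cols(tab)$cluster]]
.tab_weight <- function(tab) {
  w <- .tab_cols(tab)$weight
  if (is.null(w)) rep(1, nrow(tab)) else tab[[w]]
}
.tab_schema <- function(tab) attr(tab, "schema")

# covariate as factor with declared levels (reference first); NA kept as NA
.tab_factor <- function(tab, name) {
  sp <- .tab_schema(tab)[[name]]
  v <- as.character(tab[[name]])
  if (is.null(sp)) return(factor(v))
  factor(v, levels = c(sp$reference, setdiff(sp$levels, sp$reference)))
}

#' Build design matrices for the two marginal predictors
#'
#' Dummy-codes the requested covariates for each outcome's linear predictor:
#' an intercept column plus, for each categorical with k declared levels,
#' k-1 indicator columns against the declared reference level, in
#' declaration order then level order.  Units with a missing value in any
#' requested covariate are excluded (and indexed in `dropped`).
#'
#' @param table a `bivml_table`.
#' @param covariates1 covariate names entering outcome 1's predictor.
#' @param covariates2 covariate names entering outcome 2's predictor.
#' @return A list of class `bivml_design`: `X1`, `X2` (numeric matrices with
#'   named columns), `cluster_index` (unit -> cluster ordinal),
#'   `cluster_levels`, `y1`, `y2`, `weight`, `keep` (row indices retained
#'   from `table`), `dropped` (count excluded for missing covariates).
#' @export
encode_design <- function(table, covariates1 = character(),
                          covariates2 = character()) {
  schema <- .tab_schema(table)
  covs <- union(covariates1, covariates2)
  miss <- setdiff(covs, names(schema))
  if (length(miss))
    stop("no categorical_spec declared for: ", paste(miss, collapse = ", "),
         call. = FALSE)

  fac <- lapply(covs, function(nm) .tab_factor(table, nm))
  names(fac) <- covs
  keep <- rep(TRUE, nrow(table))
  for (f in fac) keep <- keep & !is.na(f)
  keep <- which(keep)

  one_side <- function(sel) {
    X <- matrix(1, nrow = length(keep), ncol = 1,
                dimnames = list(NULL, "(Intercept)"))
    for (nm in sel) {
      f <- factor(fac[[nm]][keep], levels = levels(fac[[nm]]))
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1])
      X <- cbind(X, m)
    }
    X
  }

  cl <- factor(.tab_cluster(table)[keep])
  structure(list(
    X1 = one_side(covariates1), X2 = one_side(covariates2),
    covariates1 = covariates1, covariates2 = covariates2,
    cluster_index = as.integer(cl), cluster_levels = levels(cl),
    y1 = .tab_y1(table)[keep], y2 = .tab_y2(table)[keep],
    weight = .tab_weight(table)[keep],
    keep = keep, dropped = nrow(table) - length(keep)),
    class = "bivml_design")
}

#' Validation report for an analysis table
#'
#' Reporting only (never errors): cluster counts and sizes, weighted outcome
#' prevalences, zero-weight units, and covariates with a single observed
#' level (non-identifiable in a regression; flagged for exclusion).
#'
#' @param table a `bivml_table`.
#' @return A list of class `bivml_validation`; serialise with
#'   [jsonlite::toJSON()] if a file report is wanted.
#' @export
validate_table <- function(table) {
  cl <- factor(.tab_cluster(table))
  w <- .tab_weight(table)
  sizes <- as.integer(table(cl))
  names(sizes) <- levels(cl)
  prev <- function(y) sum(w * y) / sum(w)
  single <- names(Filter(
    function(nm) length(unique(stats::na.omit(as.character(table[[nm]])))) < 2,
    stats::setNames(nm = names(.tab_schema(table)))))
  out <- list(
    n_units = nrow(table),
    n_clusters = nlevels(cl),
    cluster_sizes = sizes,
    prevalence_y1 = prev(.tab_y1(table)),
    prevalence_y2 = prev(.tab_y2(table)),
    zero_weight_count = sum(w == 0),
    single_level_covariates = single,
    multilevel_ok = nlevels(cl) >= 2,
    load_report = attr(table, "report"))
  class(out) <- "bivml_validation"
  out
}

#' @export
print.bivml_validation <- function(x, ...) {
  cat("Analysis table:", x$n_units, "units in", x$n_clusters, "clusters\n")
  cat(sprintf("  weighted prevalence: outcome1 %.3f, outcome2 %.3f\n",
              x$prevalence_y1, x$prevalence_y2))
  if (!x$multilevel_ok)
    cat("  ! fewer than 2 clusters: multilevel fitting unavailable\n")
  if (x$zero_weight_count)
    cat("  !", x$zero_weight_count, "zero-weight units\n")
  if (length(x$single_level_covariates))
    cat("  ! single observed level (excluded from fitting):",
        paste(x$single_level_covariates, collapse = ", "), "\n")
  invisible(x)
}
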