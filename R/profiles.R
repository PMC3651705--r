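#' Construct an isotype profile
#'
#' An isotype profile is a probability 8-tuple over the canonical
#' beta-tubulin isotypes.  It serves both as a cell-type expression profile
#' `q` and as a drug binding-affinity profile `r`.
#'
#' @param values Numeric vector of length 8.  If named, names may use any
#'   accepted isotype spelling and are re-ordered to canonical order;
#'   unnamed vectors are taken to be in canonical order.
#' @param label Free-text identifier (cell type, tissue or drug name).
#' @param normalize If `TRUE`, `values` are raw non-negative expression
#'   levels and are rescaled to sum to 1; if `FALSE` (default) they must
#'   already sum to 1 within `1e-9`.
#' @return An object of class `isotype_profile`: a named numeric vector of
#'   8 fractions summing to 1, with a `label` attribute.
#' @examples
#' isotype_profile(rep(1, 8), label = "uniform", normalize = TRUE)
#' @seealso [normalize_profile()], [argmax_isotype()]
#' @export
isotype_profile <- function(values, label = "", normalize = FALSE) {
  if (!is.numeric(values) || length(values) != 8L)
    stop("an isotype profile needs exactly 8 numeric values", call. = FALSE)
  v <- as.numeric(values)
  if (!is.null(names(values))) {
    canon <- match_isotype(names(values))
    if (anyDuplicated(canon))
      stop("duplicated isotype names in profile", call. = FALSE)
    v <- v[match(OTIP_ISOTYPES, canon)]
  }
  names(v) <- OTIP_ISOTYPES
  if (any(!is.finite(v)))
    stop("profile values must be finite", call. = FALSE)
  if (any(v < 0))
    stop("profile values must be non-negative", call. = FALSE)
  s <- sum(v)
  if (normalize) {
    if (s <= 0) stop("cannot normalize an all-zero profile", call. = FALSE)
    v <- v / s
  } else {
    if (abs(s - 1) > 1e-9)
      stop("profile values must sum to 1 (got ", format(s), "); ",
           "use normalize = TRUE for raw expression values", call. = FALSE)
    v <- v / s  # exact renormalization of rounding slack
  }
  structure(v, label = as.character(label)[1L], class = "isotype_profile")
}

#' Normalize raw expression values into an isotype profile
#'
#' @param raw Numeric vector of 8 non-negative values in arbitrary units
#'   (e.g. relative mRNA levels); at least one must be positive.
#' @param label Profile label.
#' @return An [isotype_profile()] proportional to `raw`.
#' @examples
#' normalize_profile(c(2, 1, 1, 0, 0, 0, 0, 0))
#' @export
normalize_profile <- function(raw, label = "") {
  isotype_profile(raw, label = label, normalize = TRUE)
}

is_isotype_profile <- function(x) inherits(x, "isotype_profile")

as_profile <- function(x, arg = "profile") {
  if (is_isotype_profile(x)) return(x)
  if (is.numeric(x) && length(x) == 8L) return(isotype_profile(x))
  stop(arg, " must be an isotype_profile or a numeric 8-vector",
       call. = FALSE)
}

#' @export
print.isotype_profile <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<isotype_profile>", if (nzchar(lab)) paste0(" ", sQuote(lab)), "\n",
      sep = "")
  print(round(unclass(x)[seq_len(8L)], 6))
  invisible(x)
}

#' Dominant isotype of a profile
#'
#' Returns the isotype carrying the largest fraction of the profile.  Ties
#' are broken by canonical order (the first maximal isotype wins).
#'
#' @param q An [isotype_profile()].
#' @return Canonical isotype label (character scalar).
#' @examples
#' argmax_isotype(isotype_profile(c(0.6, 0.3, 0.1, 0, 0, 0, 0, 0)))
#' @export
argmax_isotype <- function(q) {
  q <- as_profile(q, "q")
  OTIP_ISOTYPES[which.max(q)]
}

#' Construct an expression table
#'
#' A collection of isotype profiles keyed by unique labels.
#'
#' @param profiles List of [isotype_profile()] objects; names are taken
#'   from the profile labels when the list is unnamed.
#' @param source_kind One of `"cancer"`, `"healthy"`, `"drug"`.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(profiles,
                             source_kind = c("cancer", "healthy", "drug")) {
  source_kind <- match.arg(source_kind)
  if (!is.list(profiles) || length(profiles) == 0L)
    stop("profiles must be a non-empty list", call. = FALSE)
  profiles <- lapply(profiles, as_profile)
  labs <- names(profiles)
  if (is.null(labs) || any(!nzchar(labs)))
    labs <- vapply(profiles, attr, "", "label")
  if (any(!nzchar(labs)))
    stop("every profile needs a label", call. = FALSE)
  if (anyDuplicated(labs))
    stop("duplicated profile labels: ",
         paste(sQuote(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  names(profiles) <- labs
  structure(list(profiles = profiles, source_kind = source_kind),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("<expression_table> kind=", x$source_kind, ", ",
      length(x$profiles), " profile(s): ",
      paste(names(x$profiles), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an isotype expression table from a delimited file
#'
#' The file must have a header row of sample labels, with the first column
#' holding isotype names (any accepted spelling, any row order).  Values
#' are raw non-negative expression levels; every column is renormalized to
#' sum to 1.  Isotype rows absent from the file are imputed as exactly 0
#' with a warning.
#'
#' @param path File path.
#' @param delimiter Field separator (default tab).
#' @param source_kind Passed to [expression_table()].
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, delimiter = "\t",
                                  source_kind = c("cancer", "healthy",
                                                  "drug")) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2L)
    stop("expression table needs an isotype column plus >= 1 sample column",
         call. = FALSE)
  rows <- match_isotype(as.character(df[[1L]]))  # errors name unknown rows
  if (anyDuplicated(rows))
    stop("duplicated isotype rows in ", path, call. = FALSE)
  missing <- setdiff(OTIP_ISOTYPES, rows)
  if (length(missing) > 0L)
    warning("isotype row(s) absent, imputed as 0: ",
            paste(missing, collapse = ", "), call. = FALSE)
  profs <- list()
  for (j in seq(2L, ncol(df))) {
    lab <- colnames(df)[j]
    col <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(col))
      stop("non-numeric value in column ", sQuote(lab), call. = FALSE)
    v <- stats::setNames(numeric(8L), OTIP_ISOTYPES)
    v[rows] <- col
    if (any(v < 0))
      stop("negative expression value in column ", sQuote(lab),
           call. = FALSE)
    if (sum(v) <= 0)
      stop("all-zero expression column ", sQuote(lab), call. = FALSE)
    profs[[lab]] <- normalize_profile(v, label = lab)
  }
  expression_table(profs, source_kind = source_kind)
}

#' Write an expression table to a delimited file
#'
#' Inverse of [read_expression_table()]: writes the normalized fractions
#' with canonical isotype names in canonical order.
#'
#' @param tab An [expression_table()].
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tab, path, delimiter = "\t") {
  stopifnot(inherits(tab, "expression_table"))
  m <- vapply(tab$profiles, function(p) unclass(p)[OTIP_ISOTYPES],
              numeric(8L))
  df <- data.frame(isotype = OTIP_ISOTYPES, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("isotype", names(tab$profiles))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a profile to JSON
#'
#' Layout: `{"label": ..., "values": {"betaI": ..., ...}}`.
#'
#' @param q An [isotype_profile()].
#' @return A JSON string.
#' @export
profile_to_json <- function(q) {
  q <- as_profile(q, "q")
  jsonlite::toJSON(
    list(label = attr(q, "label"), values = as.list(unclass(q))),
    auto_unbox = TRUE, digits = NA
  )
}

#' Deserialize a profile from JSON
#'
#' @param txt JSON string as produced by [profile_to_json()].
#' @return An [isotype_profile()].
#' @export
profile_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  isotype_profile(unlist(obj$values), label = obj$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
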