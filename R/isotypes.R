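#' Canonical human beta-tubulin isotypes
#'
#' The eight canonical human beta-tubulin isotypes, in the fixed order used
#' throughout the package.  This order is the tie-breaking order everywhere
#' (e.g. in [argmax_isotype()]).
#'
#' @return A data frame with columns `name` (canonical isotype label,
#'   ASCII `"betaI"` ... `"betaVI"`) and `gene_symbol` (the encoding gene),
#'   paired positionally: betaV is encoded by TUBB6 and betaVI by TUBB1.
#' @examples
#' isotype_ids()
#' @export
isotype_ids <- function() {
  data.frame(
    name = OTIP_ISOTYPES,
    gene_symbol = OTIP_GENES,
    stringsAsFactors = FALSE
  )
}

OTIP_ISOTYPES <- c(
  "betaI", "betaIIa", "betaIIb", "betaIII",
  "betaIVa", "betaIVb", "betaV", "betaVI"
)

OTIP_GENES <- c(
  "TUBB", "TUBB2A", "TUBB2B", "TUBB3",
  "TUBB4A", "TUBB4B", "TUBB6", "TUBB1"
)

# alias -> canonical lookup, all keys lower-case with the Greek beta mapped
# to "beta".  Covers Greek spellings, arabic-numeral spellings and gene
# symbols (note TUBB6 -> betaV, TUBB1 -> betaVI).
otip_alias_table <- function() {
  arabic <- c("beta1", "beta2a", "beta2b", "beta3",
              "beta4a", "beta4b", "beta5", "beta6")
  keys <- c(tolower(OTIP_ISOTYPES), arabic, tolower(OTIP_GENES))
  vals <- rep(OTIP_ISOTYPES, 3L)
  stats::setNames(vals, keys)
}

#' Resolve an isotype name or alias to its canonical label
#'
#' Accepts canonical labels (`"betaIIa"`), Greek spellings (`"βIIa"`),
#' arabic-numeral spellings (`"beta2a"`) and gene symbols (`"TUBB2A"`),
#' case-insensitively.
#'
#' @param x Character vector of isotype names.
#' @return Character vector of canonical labels.
#' @export
match_isotype <- function(x) {
  stopifnot(is.character(x))
  key <- tolower(gsub("β", "beta", x))
  tab <- otip_alias_table()
  out <- tab[key]
  if (anyNA(out)) {
    bad <- x[is.na(out)]
    stop("unknown isotype name(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}
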