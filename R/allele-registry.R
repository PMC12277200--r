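## Allele registry: reading, writing and indexing star-allele definition
## tables (PharmVar/CPIC-style core alleles).

VARIANT_KEY_RE <- "^[A-Za-z0-9_.]+:[0-9]+:[ACGT]+:[ACGT]+$"

#' Parse a variant key string
#'
#' Variant keys use the \code{chrom:pos:ref:alt} convention with 1-based
#' positions matching VCF POS; indels are multi-base ref/alt strings.
#'
#' @param key Character vector of keys.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}; errors on malformed keys.
#' @export
parseVariantKey <- function(key) {
  ok <- grepl(VARIANT_KEY_RE, key)
  if (!all(ok))
    stop("malformed variant key(s): ", paste(key[!ok], collapse = ", "))
  parts <- strsplit(key, ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    ref = vapply(parts, `[`, "", 3L),
                    alt = vapply(parts, `[`, "", 4L),
                    stringsAsFactors = FALSE)
  if (any(out$pos < 1L)) stop("variant position must be >= 1")
  if (any(out$ref == out$alt)) stop("variant ref must differ from alt")
  out
}

#' Read a star-allele definition table
#'
#' Reads a tab-separated allele definition file with columns \code{gene},
#' \code{allele}, \code{variants} (semicolon-joined \code{chrom:pos:ref:alt}
#' keys, or \code{"-"} for none), \code{function}, \code{activity} and
#' optionally \code{build}. The reference allele \code{*1} must be present
#' per gene with no defining variants; the CYP2D6 whole-gene deletion
#' \code{*5} is represented as a no-function allele with no variants and
#' activity 0. Rows whose variant field does not parse are rejected with a
#' warning; structural problems (missing columns, duplicate allele names,
#' unknown function classes) are errors.
#'
#' @param path Path to the TSV file.
#' @param genes Optional character vector restricting the genes loaded.
#' @return A validated [AlleleTable-class].
#' @seealso [writeAlleleTable()], [allelesCompatibleWith()]
#' @export
#' @examples
#' tab <- readAlleleTable(system.file("extdata", "allele_definitions.tsv",
#'                                    package = "pgxCohort"))
#' nAlleles(tab)
readAlleleTable <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("allele table not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("gene", "allele", "variants", "function", "activity")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("allele table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(genes)) raw <- raw[raw$gene %in% genes, , drop = FALSE]
  build <- if ("build" %in% names(raw) && nrow(raw))
    unique(raw$build) else "unspecified"
  if (length(build) > 1L)
    stop("allele table mixes genome builds: ", paste(build, collapse = ", "))

  variants <- vector("list", nrow(raw))
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    v <- trimws(raw$variants[i])
    if (v == "-" || v == "") { variants[[i]] <- character(); next }
    keys <- strsplit(v, ";", fixed = TRUE)[[1]]
    keys <- trimws(keys)
    if (!all(grepl(VARIANT_KEY_RE, keys))) { keep[i] <- FALSE; next }
    pk <- parseVariantKey(keys)  # validates pos/ref/alt
    variants[[i]] <- sort(keys)
  }
  if (any(!keep))
    warning(sum(!keep), " allele row(s) rejected for unparseable variants: ",
            paste(paste(raw$gene[!keep], raw$allele[!keep]), collapse = ", "))
  raw <- raw[keep, , drop = FALSE]
  variants <- variants[keep]

  activity <- suppressWarnings(as.numeric(raw$activity))
  activity[raw$activity %in% c("-", "", "uncertain", "NA")] <- NA_real_
  if (any(!is.na(activity) & activity < 0))
    stop("negative activity value in allele table")

  al <- data.frame(gene = raw$gene, allele = raw$allele,
                   function_class = raw[["function"]],
                   activity = activity, stringsAsFactors = FALSE)
  al$variants <- variants
  newAlleleTable(al, build = build)
}

#' Write a star-allele definition table
#'
#' Inverse of [readAlleleTable()]; round-trips exactly.
#'
#' @param table An [AlleleTable-class].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeAlleleTable <- function(table, path) {
  al <- table@alleles
  out <- data.frame(
    gene = al$gene, allele = al$allele,
    variants = vapply(al$variants, function(v)
      if (length(v)) paste(v, collapse = ";") else "-", ""),
    `function` = al$function_class,
    activity = ifelse(is.na(al$activity), "-",
                      formatC(al$activity, format = "fg")),
    build = table@build, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Alleles compatible with an observed variant set
#'
#' Returns every allele of \code{gene} whose defining variants are a subset
#' of \code{observed}; the reference allele \code{*1} (empty defining set)
#' is always included.
#'
#' @param table An [AlleleTable-class].
#' @param gene Gene symbol.
#' @param observed Character vector of observed variant keys.
#' @return Character vector of allele names.
#' @export
allelesCompatibleWith <- function(table, gene, observed) {
  if (!gene %in% table@alleles$gene) stop("unknown gene: ", gene)
  sub <- table@alleles[table@alleles$gene == gene, ]
  ok <- vapply(sub$variants, function(v) all(v %in% observed), logical(1))
  sub$allele[ok]
}
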