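# Per-organism proteome metadata.

TAXONOMY_COLUMNS <- c("organism", "genus", "superkingdom",
                      "go_photosynthesis_count", "proteome_flags",
                      "busco_completeness")

#' Read a proteome/taxonomy metadata table (TSV)
#'
#' Required columns: organism, genus, superkingdom,
#' go_photosynthesis_count (proteins annotated with GO:0015979,
#' photosynthesis), proteome_flags (comma/semicolon-separated subset of
#' "reference", "nonredundant"; may be empty) and busco_completeness
#' (percentage; empty -> missing, never zero).
#'
#' @param path_or_text path to a TSV file, or TSV text
#' @return data.frame with one row per organism; `proteome_flags` is a
#'   list column of character vectors, `busco_completeness` numeric with
#'   NA for missing
#' @export
readTaxonomyTable <- function(path_or_text) {
  txt <- paste(path_or_text, collapse = "\n")
  if (!grepl("\n", txt) && file.exists(txt)) {
    df <- read.delim(txt, stringsAsFactors = FALSE,
                     colClasses = "character")
  } else {
    df <- read.delim(text = txt, stringsAsFactors = FALSE,
                     colClasses = "character")
  }
  missing_cols <- setdiff(TAXONOMY_COLUMNS, names(df))
  if (length(missing_cols))
    stop("taxonomy table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (any(!nzchar(df$genus))) stop("genus must be nonempty")
  sk_ok <- df$superkingdom %in% c("Archaea", "Bacteria", "Eukaryota")
  if (any(!sk_ok))
    stop("unknown superkingdom: ",
         paste(unique(df$superkingdom[!sk_ok]), collapse = ", "))
  go <- as.integer(df$go_photosynthesis_count)
  if (any(is.na(go)) || any(go < 0))
    stop("go_photosynthesis_count must be a non-negative integer")
  busco <- suppressWarnings(as.numeric(df$busco_completeness))
  busco[!nzchar(trimws(df$busco_completeness))] <- NA_real_
  if (any(!is.na(busco) & (busco < 0 | busco > 100)))
    stop("busco_completeness must lie in [0, 100]")
  flags <- lapply(strsplit(df$proteome_flags, "[,;]"), function(x) {
    x <- trimws(x)
    x <- x[nzchar(x)]
    bad <- setdiff(x, c("reference", "nonredundant"))
    if (length(bad))
      stop("unknown proteome flag: ", paste(bad, collapse = ", "))
    x
  })
  out <- data.frame(organism = df$organism, genus = df$genus,
                    superkingdom = df$superkingdom,
                    go_photosynthesis_count = go,
                    busco_completeness = busco,
                    stringsAsFactors = FALSE)
  out$proteome_flags <- flags
  out
}
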