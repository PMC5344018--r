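#' Build a species trait table
#'
#' Canonical per-species trait container: male and female body length (mm)
#' with the two derived dimorphism measures used throughout — SSD, the
#' direct difference male - female (mm), and rSSD, the ratio male/female
#' (dimensionless). Optional genital columns (aedeagus length, perimeter,
#' fractal dimension) ride along unchanged.
#'
#' @param species Character vector of species names (unique).
#' @param male_length,female_length Body lengths in mm (> 0).
#' @param ... Further per-species columns (recycled rules of data.frame).
#' @return data frame of class `trait_table` with derived `ssd` and `rssd`.
#' @export
trait_table <- function(species, male_length, female_length, ...) {
  species <- as.character(species)
  if (anyDuplicated(species))
    stop("duplicate species: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  male_length <- as.numeric(male_length)
  female_length <- as.numeric(female_length)
  if (any(!is.finite(male_length)) || any(!is.finite(female_length)))
    stop("body lengths must be finite numbers")
  if (any(male_length <= 0) || any(female_length <= 0))
    stop("body lengths must be positive (mm)")
  out <- data.frame(species = species,
                    male_length = male_length,
                    female_length = female_length,
                    ssd = male_length - female_length,
                    rssd = male_length / female_length,
                    ...,
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Read a species trait table from delimited text
#'
#' Expects at least columns `species`, `male_length`, `female_length`
#' (mm); any further columns are preserved. Field separator is sniffed
#' (comma or tab).
#'
#' @param path CSV/TSV file.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "male_length", "female_length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(need, "ssd", "rssd"))
  do.call(trait_table, c(list(species = df$species,
                              male_length = df$male_length,
                              female_length = df$female_length),
                         df[extra]))
}

#' Write a trait table to CSV
#' @param x A `trait_table` (or data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
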