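#' Lifestyle vocabulary of a dataset
#'
#' Turtles (Testudinata) are classified as terrestrial, freshwater or marine;
#' pseudosuchians (and the avemetatarsalian outgroup sampled with them) as
#' terrestrial or semi-aquatic, pooling freshwater and coastal ambush
#' predators into one amphibious category.
#'
#' @param dataset `"testudinata"` or `"pseudosuchia"`.
#' @return Character vector of admissible lifestyle labels.
#' @export
lifestyle_levels <- function(dataset = c("testudinata", "pseudosuchia")) {
  dataset <- match.arg(dataset)
  switch(dataset,
         testudinata  = c("terrestrial", "freshwater", "marine"),
         pseudosuchia = c("terrestrial", "semi-aquatic"))
}

.clade_levels <- c("Testudinata", "Pseudosuchia", "Avemetatarsalia-outgroup")

.specimen_cols <- c("specimen_id", "taxon", "clade", "porosity", "lifestyle",
                    "region", "ornamented", "age", "collection_number")

#' Read a specimen table
#'
#' Loads a delimited specimen table (one row per sampled cross section) and
#' validates it: unique specimen ids, porosity in \[0, 1\], lifestyle labels
#' drawn from the dataset's vocabulary and clades from the known set. The
#' `ornamented` column accepts yes/no or TRUE/FALSE spellings.
#'
#' @param path Path to a comma-separated file with header columns
#'   `specimen_id, taxon, clade, porosity, lifestyle, region, ornamented,
#'   age, collection_number`.
#' @param dataset Dataset label, `"testudinata"` or `"pseudosuchia"`;
#'   selects the lifestyle vocabulary used for validation.
#' @return A `data.frame` of class `"specimen_table"` with one row per
#'   specimen, `porosity` numeric and `ornamented` logical. The dataset
#'   label is kept in `attr(x, "dataset")`.
#' @seealso [specimen_fixture()] for the packaged tables,
#'   [subset_by_lifestyle()], [group_stats()].
#' @export
read_specimen_table <- function(path, dataset = c("testudinata", "pseudosuchia")) {
  dataset <- match.arg(dataset)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (!identical(names(raw), .specimen_cols))
    stop("header does not match the specimen-table schema; expected: ",
         paste(.specimen_cols, collapse = ", "))
  as_specimen_table(raw, dataset)
}

#' Coerce and validate a specimen data.frame
#'
#' @param x A data.frame with the specimen-table columns (character or
#'   already-typed).
#' @param dataset Dataset label controlling the lifestyle vocabulary.
#' @return A validated `"specimen_table"`.
#' @export
as_specimen_table <- function(x, dataset = c("testudinata", "pseudosuchia")) {
  dataset <- match.arg(dataset)
  missing_cols <- setdiff(.specimen_cols, names(x))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  x <- x[, .specimen_cols]
  n <- nrow(x)
  if (n) {
    por <- suppressWarnings(as.numeric(x$porosity))
    bad <- which(is.na(por))
    if (length(bad))
      stop("row ", bad[1], ": porosity is not numeric (",
           x$porosity[bad[1]], ")")
    out_of_range <- which(por < 0 | por > 1)
    if (length(out_of_range))
      stop("row ", out_of_range[1], ": porosity outside [0, 1] (",
           por[out_of_range[1]], ")")
    x$porosity <- por
    orn <- tolower(trimws(as.character(x$ornamented)))
    orn_lgl <- ifelse(orn %in% c("yes", "true", "1"), TRUE,
               ifelse(orn %in% c("no", "false", "0"), FALSE, NA))
    bad <- which(is.na(orn_lgl))
    if (length(bad))
      stop("row ", bad[1], ": ornamented flag not interpretable (",
           x$ornamented[bad[1]], ")")
    x$ornamented <- as.logical(orn_lgl)
    vocab <- lifestyle_levels(dataset)
    bad <- which(!x$lifestyle %in% vocab)
    if (length(bad))
      stop("row ", bad[1], ": unknown lifestyle label '",
           x$lifestyle[bad[1]], "' for dataset '", dataset, "'")
    bad <- which(!x$clade %in% .clade_levels)
    if (length(bad))
      stop("row ", bad[1], ": unknown clade '", x$clade[bad[1]], "'")
    if (anyDuplicated(x$specimen_id))
      stop("duplicate specimen_id: ",
           x$specimen_id[duplicated(x$specimen_id)][1])
  } else {
    x$porosity <- numeric(0)
    x$ornamented <- logical(0)
  }
  rownames(x) <- NULL
  class(x) <- c("specimen_table", "data.frame")
  attr(x, "dataset") <- dataset
  x
}

#' Write a specimen table
#'
#' Inverse of [read_specimen_table()]; round-trips all records.
#'
#' @param x A `"specimen_table"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(x, path) {
  stopifnot(inherits(x, "specimen_table"))
  y <- as.data.frame(x)
  y$ornamented <- ifelse(y$ornamented, "yes", "no")
  utils::write.csv(y, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged specimen tables
#'
#' The transcribed sample description tables for the two study groups:
#' 31 turtle (Testudinata) and 32 crocodylian-line (Pseudosuchia) dermal
#' plate cross sections with their measured porosity, lifestyle category,
#' anatomical region, ornamentation flag, age and collection number.
#' *Yarasuchus deccanensis* is tagged with clade
#' `"Avemetatarsalia-outgroup"` but ships inside the pseudosuchian table,
#' where it was analysed; drop it by filtering on `clade` if desired.
#'
#' @param dataset `"testudinata"` or `"pseudosuchia"`.
#' @return A `"specimen_table"`.
#' @export
specimen_fixture <- function(dataset = c("testudinata", "pseudosuchia")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0(dataset, "_specimens.csv"),
                      package = "dermovasc", mustWork = TRUE)
  read_specimen_table(path, dataset)
}

#' Subset a specimen table by lifestyle
#'
#' @param x A `"specimen_table"`.
#' @param lifestyle A label from the table's lifestyle vocabulary.
#' @return A `"specimen_table"` with exactly the matching records, in their
#'   original order (possibly zero rows).
#' @export
subset_by_lifestyle <- function(x, lifestyle) {
  stopifnot(inherits(x, "specimen_table"))
  dataset <- attr(x, "dataset")
  vocab <- lifestyle_levels(dataset)
  if (!lifestyle %in% vocab)
    stop("unknown lifestyle '", lifestyle, "' for dataset '", dataset,
         "'; expected one of: ", paste(vocab, collapse = ", "))
  out <- x[x$lifestyle == lifestyle, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("specimen_table", "data.frame")
  attr(out, "dataset") <- dataset
  out
}

#' Group specimen ids by taxon
#'
#' Returns the partition of specimen ids used by the conspecific 1-Myr tip
#' split: specimens of the same taxon form one group, keyed by the taxon's
#' tip label (the taxon name slugified the same way as the fixture trees'
#' tip labels).
#'
#' @param x A `"specimen_table"`.
#' @return Named list; names are tip labels, elements character vectors of
#'   specimen ids.
#' @export
specimen_groups <- function(x) {
  stopifnot(inherits(x, "specimen_table"))
  split(x$specimen_id, factor(taxon_slug(x$taxon), levels = unique(taxon_slug(x$taxon))))
}

#' Slugify taxon names into tip labels
#'
#' @param taxon Character vector of taxon names.
#' @return Labels safe for Newick tips (quotes, dots and parentheses
#'   stripped; spaces as underscores).
#' @export
taxon_slug <- function(taxon) {
  s <- gsub("[.'\"()]", "", taxon)
  s <- gsub("[[:space:]]+", "_", trimws(s))
  s
}

#' @export
print.specimen_table <- function(x, ...) {
  cat("Specimen table (", attr(x, "dataset"), "): ", nrow(x),
      " records\n", sep = "")
  if (nrow(x)) {
    tab <- table(x$lifestyle)
    cat("  lifestyles:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  print(as.data.frame(x), ...)
  invisible(x)
}
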