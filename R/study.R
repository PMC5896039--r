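#' Read a species-by-sample count table
#'
#' Reads a tab-separated count table (first column species identifiers,
#' header row sample identifiers) or, when the file ends in `.biom`, a BIOM
#' table via the biomformat package. Values must be non-negative integers.
#'
#' @param path Path to a TSV (or BIOM) count table.
#' @return An integer matrix, species in rows, samples in columns.
#' @seealso [write_count_table()], [join_metadata()]
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("BIOM input requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(validate_counts(m))
  }
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate species identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers in ", path)
  validate_counts(m)
}

#' Validate a count matrix
#'
#' Checks the invariants every stage relies on: non-negative integer counts,
#' unique species and sample identifiers, and strictly positive sample totals.
#'
#' @param m A numeric matrix, species in rows, samples in columns.
#' @return The matrix, coerced to integer storage, invisibly validated.
#' @export
validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must carry species row names and sample column names")
  if (anyDuplicated(rownames(m))) stop("duplicate species identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  if (anyNA(m)) stop("count matrix contains missing values")
  if (any(m < 0)) stop("negative counts are not valid")
  if (!.is_wholenumber(m)) stop("non-integer counts are not valid")
  if (any(colSums(m) <= 0))
    stop("samples with zero total counts: ",
         paste(colnames(m)[colSums(m) <= 0], collapse = ", "))
  storage.mode(m) <- "integer"
  m
}

#' Write a count table to TSV
#'
#' @param m Count matrix (species x samples).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(m, path) {
  df <- data.frame(species_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Reads a CSV with at least `sample_id`, `cohort` and `group` columns;
#' `group` must use the labels `control` and `case`. Optional columns
#' (`age`, `sex`, `bmi`, `stage`) are kept when present. Empty cells are
#' treated as missing and never imputed at read time.
#'
#' @param path CSV path.
#' @return A data frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("sample_id", "cohort", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' Join counts with sample metadata into a study object
#'
#' Keeps the samples present in both the count matrix and the metadata,
#' reporting any dropped samples. Samples with a missing cohort or group are
#' excluded. Count tables whose rows look like samples (row identifiers
#' matching the metadata sample identifiers) are rejected as transposed
#' rather than silently flipped.
#'
#' @param counts Count matrix (species x samples), see [validate_counts()].
#' @param samples Metadata data frame from [read_sample_metadata()].
#' @return An object of class `mm_study` with elements `counts` and
#'   `samples` (rows aligned with count columns).
#' @export
join_metadata <- function(counts, samples) {
  counts <- validate_counts(counts)
  if (mean(rownames(counts) %in% samples$sample_id) > 0.5)
    stop("count table appears transposed: species rows match sample ids")
  samples <- samples[!duplicated(samples$sample_id), , drop = FALSE]
  bad <- is.na(samples$cohort) | is.na(samples$group)
  if (any(bad)) {
    message("excluding ", sum(bad), " sample(s) with missing cohort/group: ",
            paste(samples$sample_id[bad], collapse = ", "))
    samples <- samples[!bad, , drop = FALSE]
  }
  keep <- intersect(colnames(counts), samples$sample_id)
  if (length(keep) == 0L) stop("no samples shared between counts and metadata")
  drop_c <- setdiff(colnames(counts), keep)
  drop_m <- setdiff(samples$sample_id, keep)
  if (length(drop_c))
    message("dropping ", length(drop_c), " count column(s) without metadata")
  if (length(drop_m))
    warning("dropping ", length(drop_m), " metadata row(s) without counts")
  counts <- counts[, keep, drop = FALSE]
  samples <- samples[match(keep, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!all(samples$group %in% c("control", "case")))
    stop("group labels must be 'control' or 'case'")
  samples$group <- factor(samples$group, levels = c("control", "case"))
  samples$cohort <- factor(samples$cohort)
  structure(list(counts = counts, samples = samples), class = "mm_study")
}

#' @export
print.mm_study <- function(x, ...) {
  tab <- table(x$samples$cohort, x$samples$group)
  cat("Multi-cohort metagenome study\n")
  cat(sprintf("  %d species x %d samples, %d cohort(s)\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$samples$cohort)))
  print(tab)
  invisible(x)
}

# split sample indices by cohort, preserving cohort level order
.cohort_index <- function(study) {
  split(seq_len(ncol(study$counts)), study$samples$cohort)
}

# relative abundance of a count matrix after adding a per-read pseudocount
.rel_log_abundance <- function(counts, pseudocount = 0.5) {
  y <- counts + pseudocount
  log(sweep(y, 2, colSums(y), "/"))
}
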