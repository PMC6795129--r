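#' Read an lncRNA-disease association table
#'
#' Reads a delimited text export of curated lncRNA-disease associations, such
#' as a LncRNADisease 2.0 download, into a record table. Columns can be
#' addressed by name or position, so arbitrary column orders and extra columns
#' are tolerated. Rows with an empty lncRNA or disease field (after whitespace
#' trimming) are rejected and counted.
#'
#' @param path Path to a TSV or CSV file.
#' @param lncrna_col Column holding lncRNA identifiers (name or 1-based
#'   position). Default `"lncRNA"` falling back to column 1 when absent.
#' @param disease_col Column holding disease identifiers. Default `"disease"`
#'   falling back to column 2.
#' @param species_col Optional column holding the species annotation; `NULL`
#'   (default) autodetects a column named `"species"` and otherwise records
#'   no species.
#' @param sep Field separator; `NULL` (default) autodetects tab vs comma from
#'   the first line.
#' @param header Does the file carry a header line? Default `TRUE`.
#' @return A data frame with columns `lncrna`, `disease`, `species` (character,
#'   `NA` when unannotated), one row per accepted input row, with attribute
#'   `n_rejected` counting rows dropped for empty identifier fields.
#' @seealso [clean_records()], [build_dataset()]
#' @export
read_associations <- function(path, lncrna_col = "lncRNA", disease_col = "disease",
                              species_col = NULL, sep = NULL, header = TRUE) {
  if (!file.exists(path)) stop_fatal("association file not found: %s", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, sep = sep, header = header, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE, colClasses = "character")
  resolve <- function(col, default_pos, required = TRUE) {
    if (is.numeric(col)) {
      if (col < 1 || col > ncol(tab)) {
        stop_fatal("column position %d out of range; file has columns: %s",
                   col, paste(colnames(tab), collapse = ", "))
      }
      return(as.integer(col))
    }
    hit <- which(colnames(tab) == col)
    if (length(hit) == 1) return(hit)
    if (!is.null(default_pos)) return(as.integer(default_pos))
    if (required) {
      stop_fatal("column '%s' not found; file has columns: %s",
                 col, paste(colnames(tab), collapse = ", "))
    }
    NA_integer_
  }
  li <- resolve(lncrna_col, if (identical(lncrna_col, "lncRNA")) 1L else NULL)
  di <- resolve(disease_col, if (identical(disease_col, "disease")) 2L else NULL)
  si <- if (is.null(species_col)) {
    hit <- which(tolower(colnames(tab)) == "species")
    if (length(hit) == 1) hit else NA_integer_
  } else {
    resolve(species_col, NULL)
  }
  out <- data.frame(
    lncrna = trimws(tab[[li]]),
    disease = trimws(tab[[di]]),
    species = if (is.na(si)) NA_character_ else trimws(tab[[si]]),
    stringsAsFactors = FALSE
  )
  bad <- !nzchar(out$lncrna) | !nzchar(out$disease) |
    is.na(out$lncrna) | is.na(out$disease)
  if (any(bad)) {
    msg(sum(bad), " row(s) rejected for empty lncRNA/disease field", level = "WARN")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Deduplicate and species-filter association records
#'
#' Curated association tables typically carry one row per supporting
#' publication, so the same (lncRNA, disease) pair recurs; only the first
#' occurrence is kept. When a species filter is given, records whose species
#' annotation does not match it (case-insensitively) are dropped; records with
#' no species annotation always survive.
#'
#' @param records Data frame as returned by [read_associations()] (columns
#'   `lncrna`, `disease`, optionally `species`).
#' @param species_filter Optional species name, e.g. `"Homo sapiens"`. `NULL`
#'   (default) keeps all species. A warning is emitted if filtering is
#'   requested but no record carries a species annotation.
#' @param lowercase Lowercase identifiers before matching? Default `FALSE`:
#'   identifiers are matched case-sensitively after trimming, so distinct
#'   capitalizations are never silently merged.
#' @return The filtered record data frame, with attributes `n_duplicates` and
#'   `n_species_removed`.
#' @export
clean_records <- function(records, species_filter = NULL, lowercase = FALSE) {
  stopifnot(is.data.frame(records), all(c("lncrna", "disease") %in% names(records)))
  rec <- records
  if (lowercase) {
    rec$lncrna <- tolower(rec$lncrna)
    rec$disease <- tolower(rec$disease)
  }
  n_sp <- 0L
  if (!is.null(species_filter)) {
    sp <- if ("species" %in% names(rec)) rec$species else rep(NA_character_, nrow(rec))
    if (all(is.na(sp))) {
      warning("species filter requested but no record has a species annotation; no-op",
              call. = FALSE)
    } else {
      keep <- is.na(sp) | tolower(sp) == tolower(species_filter)
      n_sp <- sum(!keep)
      rec <- rec[keep, , drop = FALSE]
    }
  }
  dup <- duplicated(rec[, c("lncrna", "disease")])
  n_dup <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]
  rownames(rec) <- NULL
  if (nrow(rec) == 0) warning("no records remain after cleaning", call. = FALSE)
  msg("clean_records: removed ", n_dup, " duplicate(s), ", n_sp,
      " non-matching species record(s); ", nrow(rec), " record(s) kept")
  attr(rec, "n_duplicates") <- n_dup
  attr(rec, "n_species_removed") <- n_sp
  rec
}

#' Build an indexed bipartite association dataset
#'
#' Assigns every distinct lncRNA and disease a dense integer index (in
#' lexicographic order of names, so indexing is deterministic for identical
#' input) and stores the known associations as index pairs.
#'
#' @param records Deduplicated record data frame (see [clean_records()]).
#' @return An object of class `association_dataset`: a list with `lncrna` and
#'   `disease` (character vectors; position = index), `n_l`, `n_d`, and
#'   `positives`, an integer matrix with columns `lncrna` and `disease` holding
#'   1-based indices, one row per known association.
#' @export
build_dataset <- function(records) {
  stopifnot(is.data.frame(records), all(c("lncrna", "disease") %in% names(records)))
  if (nrow(records) == 0) stop_fatal("cannot build a dataset from zero records")
  key <- paste(records$lncrna, records$disease, sep = "\r")
  if (anyDuplicated(key)) stop_fatal("records contain duplicate pairs; run clean_records() first")
  lnc <- sort(unique(records$lncrna), method = "radix")
  dis <- sort(unique(records$disease), method = "radix")
  pos <- cbind(
    lncrna = match(records$lncrna, lnc),
    disease = match(records$disease, dis)
  )
  structure(
    list(lncrna = lnc, disease = dis,
         n_l = length(lnc), n_d = length(dis),
         positives = pos),
    class = "association_dataset"
  )
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf("Bipartite association dataset: %d lncRNAs x %d diseases, %d associations (density %.4f)\n",
              x$n_l, x$n_d, nrow(x$positives),
              nrow(x$positives) / (x$n_l * x$n_d)))
  invisible(x)
}

#' Binary adjacency matrix of a dataset
#'
#' @param dataset An `association_dataset`.
#' @param positives Optional index-pair matrix to materialize instead of the
#'   dataset's full positive set (used to build per-fold training matrices).
#' @return A dense binary `n_l` x `n_d` matrix with entity names as dimnames;
#'   `A[i, j] = 1` iff lncRNA i is associated with disease j.
#' @export
to_matrix <- function(dataset, positives = dataset$positives) {
  stopifnot(inherits(dataset, "association_dataset"))
  A <- matrix(0, dataset$n_l, dataset$n_d,
              dimnames = list(dataset$lncrna, dataset$disease))
  A[positives] <- 1
  A
}

# Index-pair matrix -> character keys, for fast set membership tests.
pair_key <- function(pairs) {
  paste(pairs[, 1], pairs[, 2], sep = ":")
}

#' Write per-disease predictions as TSV
#'
#' @param predictions Data frame with columns `disease`, `lncrna`, `score`,
#'   `rank` (names, not indices).
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("disease", "lncrna", "score", "rank") %in% names(predictions)))
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a Hit-Ratio curve as metrics JSON
#'
#' Serializes as `{"HR": {"1": ..., "10": ...}}` with deterministic number
#' formatting, so identical curves produce byte-identical files.
#'
#' @param hr An `hr_curve` (see [hit_ratio()]) or a named list of curves.
#' @param path Output path.
#' @export
write_metrics <- function(hr, path) {
  as_map <- function(h) {
    stopifnot(inherits(h, "hr_curve"))
    stats::setNames(as.list(h$hr), as.character(h$cutoffs))
  }
  body <- if (inherits(hr, "hr_curve")) list(HR = as_map(hr)) else lapply(hr, as_map)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
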