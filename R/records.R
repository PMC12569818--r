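#' Mutation record tables
#'
#' A mutation dataset is a tibble with one row per wild-type/mutant/ligand
#' observation and the canonical columns:
#'
#' * `record_id` — unique identifier.
#' * `uniprot_id` — protein group label (all records of one protein share it).
#' * `wild_seq` — wild-type amino-acid sequence (20-letter alphabet plus `X`).
#' * `mutation_spec` — substitution notation such as `"T315I"` or
#'   `"G719S+T790M"` (1-based positions); may be `NA` when `mutant_seq` is
#'   given.
#' * `mutant_seq` — full mutant sequence; may be `NA` when `mutation_spec` is
#'   given.
#' * `smiles` — ligand SMILES string.
#' * `ddg` — experimental binding free energy change in kcal/mol, defined as
#'   \eqn{\Delta\Delta G = \Delta G_{Mut} - \Delta G_{WT}}; positive values
#'   weaken binding.
#' * `distance` — optional minimum residue-ligand distance in Angstrom.
#'
#' Additional columns are carried along untouched.
#'
#' @name mutation-records
NULL

CANONICAL_COLUMNS <- c("record_id", "uniprot_id", "wild_seq", "mutation_spec",
                       "mutant_seq", "smiles", "ddg", "distance")

canonical_col_types <- function() {
  readr::cols(
    record_id = readr::col_character(),
    uniprot_id = readr::col_character(),
    wild_seq = readr::col_character(),
    mutation_spec = readr::col_character(),
    mutant_seq = readr::col_character(),
    smiles = readr::col_character(),
    ddg = readr::col_double(),
    distance = readr::col_double(),
    .default = readr::col_guess()
  )
}

infer_dialect <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect != "auto") return(dialect)
  if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
}

#' Read a mutation dataset from CSV/TSV
#'
#' Parses a delimited file into a validated mutation record tibble. The
#' delimiter is inferred from the file extension (`.tsv`/`.tab`/`.txt` are
#' tab-separated, everything else comma-separated) and can be forced with
#' `dialect`. Rows are validated on read: any violation (missing mandatory
#' column, duplicate `record_id`, non-finite `ddg`, inconsistent mutation
#' specification, ...) aborts with a message naming the offending records.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect `"auto"` (default), `"csv"`, or `"tsv"`.
#' @param fasta Optional path to a FASTA file keyed by `record_id`, used to
#'   fill missing `wild_seq` entries (long sequences are often kept out of
#'   the table). Requires the Biostrings package.
#' @return A tibble of validated mutation records, in file order, with a
#'   `provenance` attribute recording the source path.
#' @seealso [write_mutation_data()], [validate_mutation_records()]
#' @export
read_mutation_data <- function(path, dialect = c("auto", "csv", "tsv"),
                               fasta = NULL) {
  if (!file.exists(path)) stop_ddg("file not found: ", path)
  dialect <- infer_dialect(path, dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  # absent canonical columns are reported by the mandatory-column check
  # below, not by the parser
  data <- withCallingHandlers(
    reader(path, col_types = canonical_col_types(), progress = FALSE),
    warning = function(w) {
      if (grepl("parsers don't match the column names", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )

  mandatory <- c("record_id", "uniprot_id", "wild_seq", "smiles", "ddg")
  if (!is.null(fasta)) mandatory <- setdiff(mandatory, "wild_seq")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols)) {
    stop_ddg("format error: missing mandatory column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(CANONICAL_COLUMNS, names(data))) {
    data[[col]] <- if (col %in% c("ddg", "distance")) NA_real_ else NA_character_
  }
  data <- data[, c(CANONICAL_COLUMNS, setdiff(names(data), CANONICAL_COLUMNS))]

  if (!is.null(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop_ddg("reading a FASTA sidecar requires the Biostrings package.")
    }
    seqs <- Biostrings::readAAStringSet(fasta)
    lookup <- setNames(as.character(seqs), names(seqs))
    fill <- is.na(data$wild_seq) & data$record_id %in% names(lookup)
    data$wild_seq[fill] <- unname(lookup[data$record_id[fill]])
  }

  assert_mutation_data(data)
  attr(data, "provenance") <- path
  data
}

#' Write a mutation dataset to CSV/TSV
#'
#' Inverse of [read_mutation_data()]: `read_mutation_data(write_mutation_data(x))`
#' reproduces `x` field by field (doubles round-trip exactly). Matrix and list
#' columns (e.g. the `feature` column added by [featurize_mutation_data()])
#' are dropped from the file.
#'
#' @param data A mutation record tibble.
#' @param path Output file path.
#' @inheritParams read_mutation_data
#' @return `path`, invisibly.
#' @export
write_mutation_data <- function(data, path, dialect = c("auto", "csv", "tsv")) {
  assert_mutation_data(data)
  dialect <- infer_dialect(path, dialect)
  flat <- data[, vapply(data, function(col) is.atomic(col) && !is.matrix(col),
                        logical(1)), drop = FALSE]
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(flat, path, progress = FALSE)
  invisible(path)
}

#' Validate mutation records
#'
#' Checks every record against the dataset invariants and returns the
#' violations as a tibble instead of raising: validation is total and never
#' errors on malformed-but-parseable input. An empty result means the data
#' are valid.
#'
#' Checked rules: unique `record_id`; non-empty `wild_seq` over the amino
#' acid alphabet (plus `X`); finite `ddg`; at least one of
#' `mutation_spec`/`mutant_seq`; parseable `mutation_spec` with 1-based
#' positions inside the sequence, matching stated wild residues and no
#' duplicated positions; `mutant_seq` of equal length to `wild_seq`
#' (substitutions only); non-negative `distance`; non-empty `smiles`.
#'
#' @param data A mutation record tibble (see [mutation-records]).
#' @return A tibble with columns `record_id`, `field`, `rule`, `message`;
#'   zero rows when all invariants hold.
#' @export
validate_mutation_records <- function(data) {
  if (!is.data.frame(data)) stop_ddg("`data` must be a data frame.")
  out <- list()
  add <- function(record_id, field, rule, message) {
    out[[length(out) + 1L]] <<- tibble(
      record_id = as.character(record_id), field = field,
      rule = rule, message = message
    )
  }
  missing_cols <- setdiff(CANONICAL_COLUMNS, names(data))
  if (length(missing_cols)) {
    add(NA_character_, paste(missing_cols, collapse = ","), "missing_column",
        paste("missing canonical column(s):", paste(missing_cols, collapse = ", ")))
    return(bind_rows(out))
  }

  dup <- data$record_id[duplicated(data$record_id)]
  for (id in unique(dup)) {
    add(id, "record_id", "duplicate_record_id",
        paste0("record_id '", id, "' appears more than once"))
  }

  for (i in seq_len(nrow(data))) {
    id <- data$record_id[i]
    ws <- data$wild_seq[i]
    if (is.na(id) || !nzchar(id)) add(id, "record_id", "empty", "record_id is empty")
    if (is.na(ws) || !nzchar(ws)) {
      add(id, "wild_seq", "empty", "wild_seq is empty")
      next
    }
    bad <- setdiff(unique(strsplit(ws, "")[[1]]), AA_ALPHABET_X)
    if (length(bad)) {
      add(id, "wild_seq", "alphabet",
          paste0("invalid residue(s) in wild_seq: ", paste(bad, collapse = "")))
    }
    if (!is.finite(data$ddg[i])) {
      add(id, "ddg", "finite", "ddg must be a finite number")
    }
    if (!is.na(data$distance[i]) &&
        (!is.finite(data$distance[i]) || data$distance[i] < 0)) {
      add(id, "distance", "non_negative", "distance must be >= 0")
    }
    if (is.na(data$smiles[i]) || !nzchar(data$smiles[i])) {
      add(id, "smiles", "empty", "smiles is empty")
    }
    spec <- data$mutation_spec[i]
    mseq <- data$mutant_seq[i]
    if (is.na(spec) && is.na(mseq)) {
      add(id, "mutation_spec", "one_of_spec_or_seq",
          "one of mutation_spec or mutant_seq is required")
    }
    if (!is.na(spec)) {
      parsed <- tryCatch(parse_mutation_spec(spec), error = function(e) e)
      if (inherits(parsed, "error")) {
        add(id, "mutation_spec", "parse",
            conditionMessage(parsed))
      } else {
        if (anyDuplicated(parsed$pos)) {
          add(id, "mutation_spec", "duplicate_position",
              "mutation_spec repeats a position")
        }
        oob <- parsed$pos[parsed$pos < 1 | parsed$pos > nchar(ws)]
        if (length(oob)) {
          add(id, "mutation_spec", "position_out_of_range",
              paste0("position(s) ", paste(oob, collapse = ","),
                     " outside 1..", nchar(ws)))
        } else {
          actual <- substring(ws, parsed$pos, parsed$pos)
          mism <- which(actual != parsed$wt)
          for (j in mism) {
            add(id, "mutation_spec", "wild_residue_mismatch",
                paste0("position ", parsed$pos[j], ": wild_seq has '",
                       actual[j], "' but spec states '", parsed$wt[j], "'"))
          }
        }
      }
    }
    if (!is.na(mseq)) {
      if (nchar(mseq) != nchar(ws)) {
        add(id, "mutant_seq", "length",
            "mutant_seq must have the same length as wild_seq (substitutions only)")
      }
      badm <- setdiff(unique(strsplit(mseq, "")[[1]]), AA_ALPHABET_X)
      if (length(badm)) {
        add(id, "mutant_seq", "alphabet",
            paste0("invalid residue(s) in mutant_seq: ", paste(badm, collapse = "")))
      }
    }
  }
  if (!length(out)) {
    return(tibble(record_id = character(), field = character(),
                  rule = character(), message = character()))
  }
  bind_rows(out)
}

# Abort with a readable summary when a dataset fails validation.
assert_mutation_data <- function(data) {
  violations <- validate_mutation_records(data)
  if (nrow(violations)) {
    shown <- head(violations, 5L)
    lines <- paste0("  - [", shown$record_id, "] ", shown$field, ": ",
                    shown$message)
    more <- if (nrow(violations) > 5L) {
      paste0("\n  ... and ", nrow(violations) - 5L, " more")
    } else ""
    stop_ddg("invalid mutation records (", nrow(violations), " violation(s)):\n",
             paste(lines, collapse = "\n"), more)
  }
  invisible(data)
}
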