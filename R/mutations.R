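# Mutation specification parsing and application.

# Parse "T315I" / "G719S+T790M" into wild residue, 1-based position, and
# replacement residue. Whitespace around "+" is tolerated.
parse_mutation_spec <- function(spec) {
  if (is.na(spec) || !nzchar(trimws(spec))) {
    stop_ddg("empty mutation spec")
  }
  tokens <- trimws(strsplit(spec, "+", fixed = TRUE)[[1]])
  m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
  bad <- tokens[vapply(m, length, integer(1)) == 0L]
  if (length(bad)) {
    stop_ddg("cannot parse mutation token(s): ", paste(bad, collapse = ", "))
  }
  list(
    wt = toupper(vapply(m, `[[`, character(1), 2L)),
    pos = as.integer(vapply(m, `[[`, character(1), 3L)),
    mut = toupper(vapply(m, `[[`, character(1), 4L))
  )
}

#' Apply point mutations to a wild-type sequence
#'
#' Builds the mutant amino-acid sequence from a wild-type sequence and a
#' substitution specification in standard notation (`"T315I"`, multiple
#' substitutions joined by `"+"` as in `"G719S+T790M"`). Positions are
#' 1-based. Only substitutions are supported, so the returned sequence has
#' the same length as the input and differs exactly at the specified
#' positions (self-substitutions such as `"A1A"` are allowed and leave the
#' sequence unchanged at that position).
#'
#' @param wild_seq Character vector of wild-type sequences.
#' @param spec Character vector of mutation specifications, recycled against
#'   `wild_seq`.
#' @return Character vector of mutant sequences.
#' @examples
#' apply_mutations("ACDT", "T4I")
#' apply_mutations("ACDT", "A1A")
#' @export
apply_mutations <- function(wild_seq, spec) {
  n <- max(length(wild_seq), length(spec))
  wild_seq <- rep_len(wild_seq, n)
  spec <- rep_len(spec, n)
  vapply(seq_len(n), function(i) {
    apply_mutations_one(wild_seq[i], spec[i])
  }, character(1))
}

apply_mutations_one <- function(wild_seq, spec) {
  parsed <- parse_mutation_spec(spec)
  if (anyDuplicated(parsed$pos)) {
    stop_ddg("mutation spec '", spec, "' repeats position ",
             parsed$pos[duplicated(parsed$pos)][1])
  }
  len <- nchar(wild_seq)
  oob <- parsed$pos[parsed$pos < 1 | parsed$pos > len]
  if (length(oob)) {
    stop_ddg("mutation position ", oob[1], " outside 1..", len)
  }
  actual <- substring(wild_seq, parsed$pos, parsed$pos)
  mism <- which(actual != parsed$wt)
  if (length(mism)) {
    stop_ddg("wild-residue mismatch at position ", parsed$pos[mism[1]],
             ": sequence has '", actual[mism[1]], "', spec states '",
             parsed$wt[mism[1]], "'")
  }
  chars <- strsplit(wild_seq, "")[[1]]
  chars[parsed$pos] <- parsed$mut
  paste(chars, collapse = "")
}

# Fill mutant_seq from wild_seq + mutation_spec where absent.
fill_mutant_seq <- function(data) {
  needs <- is.na(data$mutant_seq)
  if (any(needs)) {
    data$mutant_seq[needs] <- apply_mutations(data$wild_seq[needs],
                                              data$mutation_spec[needs])
  }
  data
}
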