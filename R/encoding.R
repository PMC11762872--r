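# 12-letter sequence-structure encoding.
#
# Each nucleotide carries one of three pairing states -- unpaired,
# paired-left ('('), paired-right (')') -- giving 4 x 3 = 12 characters.
# The concrete letter assignment is arbitrary (downstream scores, distances
# and likelihoods are invariant under relabeling) but fixed and versioned:
#   unpaired     A C G U -> A C G U
#   paired-left  A C G U -> B D H V
#   paired-right A C G U -> E F I W
# 'N' is allowed only unpaired and is encoded as the wildcard 'X', which is
# excluded from distance and likelihood counts.

SS_STATES <- c("unpaired", "left", "right")
SS_WILDCARD <- "X"
SS_GAP <- "-"

#' The 12-letter sequence-structure translation table
#'
#' Bijection between (nucleotide, pairing state) and the 12-letter
#' alphabet. Custom tables may be supplied anywhere a `table` argument is
#' accepted, as long as they pass [validate_translation_table()].
#'
#' @param version identifier stored with the table.
#' @return data.frame with columns `nuc`, `state`, `symbol` and class
#'   `ss_translation_table`.
#' @examples
#' tab <- translation_table()
#' nrow(tab)  # 12
#' @export
translation_table <- function(version = "ssphylo-1") {
  tab <- data.frame(
    nuc = rep(NUCS, times = 3),
    state = rep(SS_STATES, each = 4),
    symbol = c("A", "C", "G", "U",  "B", "D", "H", "V",  "E", "F", "I", "W"),
    stringsAsFactors = FALSE
  )
  attr(tab, "version") <- version
  class(tab) <- c("ss_translation_table", "data.frame")
  validate_translation_table(tab)
  tab
}

#' Validate a translation table
#'
#' Checks that the table is a total bijection: every (nucleotide, state)
#' combination appears exactly once and the 12 symbols are distinct single
#' characters, none of them the gap or wildcard character.
#' @param table candidate table.
#' @return the table, invisibly; errors if invalid.
#' @export
validate_translation_table <- function(table) {
  if (nrow(table) != 12L) stopf("translation table must have 12 rows")
  keys <- paste(table$nuc, table$state)
  want <- paste(rep(NUCS, times = 3), rep(SS_STATES, each = 4))
  if (!setequal(keys, want) || anyDuplicated(keys))
    stopf("translation table must cover each (nucleotide, state) exactly once")
  if (anyDuplicated(table$symbol) || any(nchar(table$symbol) != 1L))
    stopf("translation table symbols must be 12 distinct single characters")
  if (any(table$symbol %in% c(SS_GAP, SS_WILDCARD)))
    stopf("translation table symbols may not include '%s' or '%s'",
          SS_GAP, SS_WILDCARD)
  invisible(table)
}

#' The 12-letter alphabet of a translation table
#' @param table a translation table.
#' @return character vector of 12 symbols, in table order.
#' @export
ss_alphabet <- function(table = translation_table()) table$symbol

structure_states <- function(structure, id = "<record>") {
  cs <- chars(structure)
  st <- rep(NA_character_, length(cs))
  st[cs == "."] <- "unpaired"
  st[cs == "("] <- "left"
  st[cs == ")"] <- "right"
  if (anyNA(st))
    stopf("record '%s': invalid structure character", id)
  st
}

#' Encode one sequence-structure pair
#'
#' @param seq nucleotide string over A,C,G,U,N.
#' @param structure same-length dot-bracket string.
#' @param table translation table.
#' @param id record id used in error messages.
#' @return string over the 12-letter alphabet (plus `X` for unpaired N).
#' @examples
#' encode_pair("ACGU", "(..)")  # "BCGW"
#' @export
encode_pair <- function(seq, structure, table = translation_table(),
                        id = "<record>") {
  seq <- normalize_seq(seq)
  validate_pair(seq, structure, id)
  if (nchar(seq) == 0L) return("")
  st <- structure_states(structure, id)
  cs <- chars(seq)
  out <- character(length(cs))
  isn <- cs == "N"
  if (any(isn & st != "unpaired"))
    stopf("record '%s': 'N' at a paired position (position %d)", id,
          which(isn & st != "unpaired")[1] - 1L)
  out[isn] <- SS_WILDCARD
  key <- paste(table$nuc, table$state)
  lut <- stats::setNames(table$symbol, key)
  out[!isn] <- lut[paste(cs[!isn], st[!isn])]
  collapse(out)
}

#' Decode a 12-letter string back to sequence + structure
#'
#' Inverse of [encode_pair()]; errors if the implied bracket string is not
#' balanced or a symbol is outside the alphabet.
#' @param symbols encoded string.
#' @param table translation table.
#' @param id record id used in error messages.
#' @return list with elements `seq` and `structure`.
#' @export
decode_pair <- function(symbols, table = translation_table(),
                        id = "<record>") {
  if (nchar(symbols) == 0L) return(list(seq = "", structure = ""))
  cs <- chars(symbols)
  bad <- setdiff(unique(cs), c(table$symbol, SS_WILDCARD))
  if (length(bad) > 0)
    stopf("record '%s': symbol(s) outside the 12-letter alphabet: %s", id,
          paste(bad, collapse = ", "))
  nuc <- stats::setNames(table$nuc, table$symbol)[cs]
  st <- stats::setNames(table$state, table$symbol)[cs]
  nuc[cs == SS_WILDCARD] <- "N"
  st[cs == SS_WILDCARD] <- "unpaired"
  br <- c(unpaired = ".", left = "(", right = ")")[st]
  structure <- collapse(br)
  db_pairs(structure, id)  # balanced-brackets check
  list(seq = collapse(nuc), structure = structure)
}

#' Encode a collection of sequence-structure pairs
#'
#' @param pairs data.frame with columns `id`, `seq`, `structure` (extra
#'   columns are carried along unchanged).
#' @param table translation table.
#' @return data.frame with columns `id`, `symbols`.
#' @export
encode_pairs <- function(pairs, table = translation_table()) {
  stopifnot(is.data.frame(pairs), all(c("id", "seq", "structure") %in% names(pairs)))
  sym <- vapply(seq_len(nrow(pairs)), function(i)
    encode_pair(pairs$seq[i], pairs$structure[i], table, id = pairs$id[i]),
    character(1))
  data.frame(id = pairs$id, symbols = sym, stringsAsFactors = FALSE)
}

#' Decode a collection of encoded sequences
#' @param enc data.frame with columns `id`, `symbols`.
#' @param table translation table.
#' @return data.frame with columns `id`, `seq`, `structure`.
#' @export
decode_pairs <- function(enc, table = translation_table()) {
  stopifnot(is.data.frame(enc), all(c("id", "symbols") %in% names(enc)))
  dec <- lapply(seq_len(nrow(enc)), function(i)
    decode_pair(enc$symbols[i], table, id = enc$id[i]))
  data.frame(id = enc$id,
             seq = vapply(dec, `[[`, character(1), "seq"),
             structure = vapply(dec, `[[`, character(1), "structure"),
             stringsAsFactors = FALSE)
}

#' Dump a translation table as TSV
#' @param table translation table.
#' @param path output file.
#' @export
write_translation_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
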