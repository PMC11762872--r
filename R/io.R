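# On-disk formats: FASTA, xfasta (sequence + dot-bracket structure),
# 1-letter-encoded FASTA, Newick, fold-constraint files.
#
# xfasta dialect (defined here; multi-line blocks allowed):
#   >id description
#   <sequence lines>
#   <structure lines>
# All sequence lines of an entry precede all structure lines; the two
# blocks must have equal total length. Structure lines contain only
# '(', ')', '.'.

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and T is normalized to U. The header's first
#' token is the record id; the remainder is the description. `taxon_name`
#' is the description when present, else the id with underscores replaced
#' by spaces.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `description`, `taxon_name`, `seq`
#'   (in file order).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (any(!nzchar(id)))
    stopf("malformed FASTA header (empty id) at record %d", which(!nzchar(id))[1])
  if (anyDuplicated(id))
    stopf("duplicate FASTA id: '%s'", id[duplicated(id)][1])
  seqs <- normalize_seq(as.character(set))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stopf("record '%s': empty sequence", id[i])
    check_seq_alphabet(seqs[i], id[i])
  }
  data.frame(id = id, description = desc,
             taxon_name = ifelse(nzchar(desc), desc, gsub("_", " ", id)),
             seq = unname(seqs), stringsAsFactors = FALSE)
}

fasta_header <- function(id, description) {
  description <- rep_len(description, length(id))
  ifelse(nzchar(description), paste0(">", id, " ", description),
         paste0(">", id))
}

#' Write sequences as FASTA
#' @param records data.frame with columns `id`, `seq` (optional `description`).
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  desc <- if ("description" %in% names(records)) records$description else ""
  lines <- as.vector(rbind(fasta_header(records$id, desc), records$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Read an xfasta file of sequence-structure pairs
#'
#' @param path xfasta file (dialect described above).
#' @return data.frame with columns `id`, `description`, `taxon_name`,
#'   `seq`, `structure`; every pair validated (equal lengths, balanced
#'   nested brackets).
#' @export
read_xfasta <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(id = character(0), description = character(0),
                      taxon_name = character(0), seq = character(0),
                      structure = character(0), stringsAsFactors = FALSE))
  if (!startsWith(lines[1], ">")) stopf("xfasta: first line must be a '>' header")
  starts <- which(startsWith(lines, ">"))
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- sub("^>", "", lines[starts[k]])
    id <- sub("\\s.*$", "", hdr)
    desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
    if (!nzchar(id)) stopf("xfasta: empty id in entry %d", k)
    body <- lines[seq(starts[k] + 1L, length.out = ends[k] - starts[k])]
    if (length(body) == 0L) stopf("xfasta: record '%s' has no body", id)
    is_struct <- grepl("^[().]+$", body)
    if (!any(is_struct)) stopf("xfasta: record '%s' has no structure block", id)
    if (any(diff(is_struct) < 0))
      stopf("xfasta: record '%s': sequence line after structure block", id)
    seq <- normalize_seq(collapse(body[!is_struct]))
    structure <- collapse(body[is_struct])
    validate_pair(seq, structure, id)
    out[[k]] <- data.frame(id = id, description = desc,
                           taxon_name = ifelse(nzchar(desc), desc, gsub("_", " ", id)),
                           seq = seq, structure = structure,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (anyDuplicated(res$id)) stopf("duplicate xfasta id: '%s'",
                                   res$id[duplicated(res$id)][1])
  rownames(res) <- NULL
  res
}

#' Write sequence-structure pairs as xfasta
#' @param pairs data.frame with columns `id`, `seq`, `structure` (optional
#'   `description`).
#' @param path output file.
#' @export
write_xfasta <- function(pairs, path) {
  desc <- if ("description" %in% names(pairs)) pairs$description else ""
  for (i in seq_len(nrow(pairs)))
    validate_pair(pairs$seq[i], pairs$structure[i], pairs$id[i])
  lines <- as.vector(rbind(fasta_header(pairs$id, desc), pairs$seq,
                           pairs$structure))
  writeLines(lines, path)
  invisible(path)
}

#' Read 1-letter-encoded FASTA
#'
#' @param path FASTA of encoded strings.
#' @param table translation table defining the accepted alphabet; gaps
#'   (`-`) and the wildcard are also accepted.
#' @return data.frame with columns `id`, `symbols`.
#' @export
read_encoded_fasta <- function(path, table = translation_table()) {
  set <- Biostrings::readBStringSet(path)
  id <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(id)) stopf("duplicate id: '%s'", id[duplicated(id)][1])
  sym <- as.character(set)
  ok <- c(table$symbol, SS_WILDCARD, SS_GAP)
  for (i in seq_along(sym)) {
    bad <- setdiff(unique(chars(sym[i])), ok)
    if (length(bad) > 0)
      stopf("record '%s': symbol(s) outside the encoded alphabet: %s",
            id[i], paste(bad, collapse = ", "))
  }
  data.frame(id = id, symbols = unname(sym), stringsAsFactors = FALSE)
}

#' Write 1-letter-encoded FASTA
#' @param enc data.frame with columns `id`, `symbols`.
#' @param path output file.
#' @param table translation table defining the accepted alphabet.
#' @export
write_encoded_fasta <- function(enc, path, table = translation_table()) {
  ok <- c(table$symbol, SS_WILDCARD, SS_GAP)
  for (i in seq_len(nrow(enc))) {
    bad <- setdiff(unique(chars(enc$symbols[i])), ok)
    if (length(bad) > 0)
      stopf("record '%s': symbol(s) outside the encoded alphabet: %s",
            enc$id[i], paste(bad, collapse = ", "))
  }
  if (nrow(enc) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(as.vector(rbind(paste0(">", enc$id), enc$symbols)), path)
  invisible(path)
}

# minimal Newick scanner so parse errors carry a 0-based position
scan_newick <- function(text) {
  cs <- chars(text)
  depth <- 0L
  prev <- ""
  for (i in seq_along(cs)) {
    c <- cs[i]
    if (c == "(") depth <- depth + 1L
    if (c == ")") {
      depth <- depth - 1L
      if (depth < 0L) stopf("newick: unbalanced ')' at position %d", i - 1L)
      if (prev == ",") stopf("newick: dangling comma at position %d", i - 2L)
    }
    if (c == "," && prev %in% c("", "(", ","))
      stopf("newick: empty item before comma at position %d", i - 1L)
    if (c == ";" && depth != 0L)
      stopf("newick: unbalanced '(' at position %d", i - 1L)
    if (!c %in% c(" ", "\t")) prev <- c
  }
  if (depth != 0L) stopf("newick: unbalanced '(' at position %d",
                         length(cs) - 1L)
  if (prev != ";") stopf("newick: missing terminal ';' at position %d",
                         length(cs) - 1L)
  invisible(TRUE)
}

#' Read a Newick tree
#'
#' Integer internal node labels are read as bootstrap support values (the
#' dominant convention) and kept in `node.label`.
#' @param path file containing one Newick tree.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  text <- paste(trimws(readLines(path)), collapse = "")
  scan_newick(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stopf("newick: parse failure")
  if (anyDuplicated(tree$tip.label))
    stopf("newick: duplicate leaf label '%s'",
          tree$tip.label[duplicated(tree$tip.label)][1])
  tree
}

#' Write a Newick tree
#'
#' Internal node labels (support values) are preserved. With
#' `hide_support_at_or_below`, labels that are integers less than or equal
#' to the cutoff are blanked in the output (display convention; the tree
#' object keeps all values).
#' @param tree an `ape::phylo` tree.
#' @param path output file.
#' @param hide_support_at_or_below optional numeric cutoff (e.g. 50).
#' @export
write_newick <- function(tree, path, hide_support_at_or_below = NULL) {
  if (!is.null(hide_support_at_or_below) && !is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    hide <- !is.na(lab) & lab <= hide_support_at_or_below
    tree$node.label[hide] <- ""
  }
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a fold-constraint file
#'
#' One item per line: either a single 0-based position `i` or a half-open
#' range `a-b` (positions a, ..., b-1). `#` starts a comment. The listed
#' positions are forbidden to pair during constrained folding (the
#' central-ring convention).
#' @param path constraint file.
#' @param seq_length length of the target sequence; positions are checked
#'   against `[0, seq_length)`.
#' @return sorted integer vector of forbidden 0-based positions.
#' @export
read_constraints <- function(path, seq_length) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  pos <- integer(0)
  for (ln in lines) {
    if (grepl("^[0-9]+-[0-9]+$", ln)) {
      ab <- as.integer(strsplit(ln, "-", fixed = TRUE)[[1]])
      if (ab[2] <= ab[1]) stopf("constraints: empty range '%s'", ln)
      pos <- c(pos, seq(ab[1], ab[2] - 1L))
    } else if (grepl("^[0-9]+$", ln)) {
      pos <- c(pos, as.integer(ln))
    } else {
      stopf("constraints: cannot parse line '%s'", ln)
    }
  }
  pos <- sort(unique(pos))
  if (length(pos) > 0 && (min(pos) < 0L || max(pos) >= seq_length))
    stopf("constraints: position %d outside [0, %d)",
          pos[pos < 0L | pos >= seq_length][1], seq_length)
  pos
}

#' Write a fold-constraint file
#' @param positions integer vector of forbidden 0-based positions.
#' @param path output file.
#' @export
write_constraints <- function(positions, path) {
  writeLines(as.character(sort(unique(as.integer(positions)))), path)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#' @param D symmetric numeric matrix with labels as dimnames.
#' @param path output file.
#' @export
write_phylip_dist <- function(D, path) {
  n <- nrow(D)
  lab <- rownames(D)
  rows <- vapply(seq_len(n), function(i)
    paste(formatC(lab[i], width = -10), paste(fmt_num(D[i, ]), collapse = " ")),
    character(1))
  writeLines(c(sprintf("%5d", n), rows), path)
  invisible(path)
}
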