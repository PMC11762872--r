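# Pipeline orchestration: filters, structure prediction, encoding,
# alignment, trees, bootstrap and rooting as one configured, seeded run
# with a per-record manifest (kept/discarded + machine-readable reasons).
#
# Reason codes: not_binomial, annotation_failed, truncated_proximal_stem,
# low_structural_homology, user_excluded.

#' Pipeline run configuration
#'
#' @param cistrons input records: a data.frame (`id`, `seq`, `taxon_name`)
#'   or a FASTA path.
#' @param templates homology-modeling templates: a data.frame (`id`,
#'   `seq`, `structure`) or an xfasta path (required for homology modes).
#' @param hmms list with `hmm5`, `hmm3` ([default_flank_hmms()]).
#' @param require_binomial_species drop records whose taxon name is not a
#'   clean binomial.
#' @param require_full_proximal_stem drop records not annotatable by the
#'   full proximal stem.
#' @param min_transfer_percent structure-transfer filter threshold
#'   (inclusive; paper value 50).
#' @param structure_mode `"homology_then_fold"` (homology filter, then
#'   individualized constrained folding with the modeled central ring
#'   forbidden to pair), `"homology"`, or `"constrained_fold"`.
#' @param constraints for `"constrained_fold"` mode: named list of 0-based
#'   forbidden-position vectors per record id (default none).
#' @param exclude_ids records discarded up front (`user_excluded`).
#' @param proximal_L proximal-stem extension (nt).
#' @param log_odds_floor annotation score floor.
#' @param scoring 12x12 scoring model for alignment.
#' @param tree_methods subset of `c("nj", "mp", "ml")` (>= 1).
#' @param model substitution model for ML and distances.
#' @param bootstrap_B bootstrap pseudo-replicates (paper default 100; 0
#'   skips the bootstrap, the overview-tree preset).
#' @param outgroup outgroup tip ids for rooting (NULL leaves trees
#'   unrooted).
#' @param min_taxa abort threshold: fewer survivors than this aborts the
#'   run with a complete manifest.
#' @param seed run seed (drives the bootstrap resampling).
#' @param out_dir artifact directory (NULL: no files written).
#' @return list of class `ss_run_config`.
#' @export
run_config <- function(cistrons, templates = NULL,
                       hmms = default_flank_hmms(),
                       require_binomial_species = TRUE,
                       require_full_proximal_stem = TRUE,
                       min_transfer_percent = 50,
                       structure_mode = c("homology_then_fold", "homology",
                                          "constrained_fold"),
                       constraints = NULL, exclude_ids = character(0),
                       proximal_L = 25, log_odds_floor = 0,
                       scoring = scoring_model12(),
                       tree_methods = "nj", model = model_jc12(),
                       bootstrap_B = 100, outgroup = NULL, min_taxa = 4,
                       seed = 42, out_dir = NULL) {
  structure_mode <- match.arg(structure_mode)
  tree_methods <- match.arg(tree_methods, c("nj", "mp", "ml"),
                            several.ok = TRUE)
  if (length(tree_methods) < 1) stopf("run_config: need >= 1 tree method")
  if (min_transfer_percent < 0 || min_transfer_percent > 100)
    stopf("run_config: min_transfer_percent must lie in [0, 100]")
  obj <- as.list(environment())
  class(obj) <- "ss_run_config"
  obj
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [run_config()] may be given in the file; `cistrons`
#' and `templates` are paths.
#' @param path YAML file.
#' @return an `ss_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)),
                   c("hmms", "scoring", "model", "constraints"))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0)
    stopf("read_run_config: unknown field(s): %s", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' Filter records to clean binomial species names
#'
#' Keeps records whose `taxon_name` is two words -- a capitalized genus
#' and a lowercase epithet -- with the epithet not an open-nomenclature or
#' environmental marker (sp., cf., aff., uncultured, environmental).
#' @param records data.frame with a `taxon_name` column.
#' @return list with `kept` and `discarded` (reason `not_binomial`).
#' @export
filter_species_named <- function(records) {
  name <- records$taxon_name
  words <- strsplit(trimws(name), "\\s+")
  ok <- vapply(words, function(w) {
    if (length(w) != 2) return(FALSE)
    if (!grepl("^[A-Z][a-z]+$", w[1])) return(FALSE)
    if (!grepl("^[a-z][a-z-]*$", w[2])) return(FALSE)
    !tolower(sub("\\.$", "", w[2])) %in%
      c("sp", "cf", "aff", "uncultured", "environmental")
  }, logical(1))
  discarded <- records[!ok, , drop = FALSE]
  if (nrow(discarded) > 0) discarded$reason <- "not_binomial"
  list(kept = records[ok, , drop = FALSE], discarded = discarded)
}

load_records <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full sequence-structure pipeline
#'
#' Stages, in order: user exclusions; species-name filter; ITS2
#' annotation and proximal-stem filter; structure prediction and the
#' structural-homology filter; 12-letter encoding; progressive alignment;
#' tree reconstruction per method; bootstrap; outgroup rooting; support
#' mapping; artifact writing. The manifest accounts for every input
#' record at every stage (kept + discarded = input).
#'
#' @param config an [run_config()].
#' @return list with `manifest` (data.frame), `aborted`, `pairs`
#'   (predicted structures), `encoded`, `alignment`, `trees` (named list
#'   of support-annotated, possibly rooted `phylo`), `counts` (per-stage
#'   data.frame).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ss_run_config"))
  records <- load_records(config$cistrons, read_fasta)
  if (!"taxon_name" %in% names(records)) records$taxon_name <- records$id
  manifest <- data.frame(id = records$id, taxon_name = records$taxon_name,
                         kept = TRUE, reason = NA_character_,
                         its2_start = NA_integer_, its2_end = NA_integer_,
                         template = NA_character_,
                         transfer_percent = NA_real_,
                         stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    hit <- manifest$id %in% ids & manifest$kept
    manifest$kept[hit] <<- FALSE
    manifest$reason[hit] <<- reason
  }
  counts <- list(c(stage = "input", kept = nrow(records)))
  note <- function(stage) counts[[length(counts) + 1L]] <<-
    c(stage = stage, kept = sum(manifest$kept))

  if (length(config$exclude_ids) > 0) drop(config$exclude_ids, "user_excluded")
  note("user_exclusions")

  live <- function() records[records$id %in% manifest$id[manifest$kept], ,
                             drop = FALSE]
  if (isTRUE(config$require_binomial_species)) {
    fs <- filter_species_named(live())
    if (nrow(fs$discarded) > 0) drop(fs$discarded$id, "not_binomial")
  }
  note("species_filter")

  ann <- annotate_sequences(live(), config$hmms$hmm5, config$hmms$hmm3,
                            L = config$proximal_L,
                            floor = config$log_odds_floor)
  fa <- filter_annotatable(ann)
  keep_ann <- if (isTRUE(config$require_full_proximal_stem)) fa$kept
              else ann[ann$ok, , drop = FALSE]
  if (isTRUE(config$require_full_proximal_stem)) {
    for (r in seq_len(nrow(fa$discarded)))
      drop(fa$discarded$id[r], fa$discarded$reason[r])
  } else {
    drop(ann$id[!ann$ok], "annotation_failed")
  }
  m <- match(keep_ann$id, manifest$id)
  manifest$its2_start[m] <- keep_ann$its2_start
  manifest$its2_end[m] <- keep_ann$its2_end
  note("annotation_filter")

  # ITS2 subsequences of surviving records (1-based substr from 0-based)
  lv <- live()
  ai <- match(lv$id, manifest$id)
  its2 <- data.frame(
    id = lv$id, taxon_name = lv$taxon_name,
    seq = substr(lv$seq, manifest$its2_start[ai] + 1L, manifest$its2_end[ai]),
    stringsAsFactors = FALSE)

  mode <- config$structure_mode
  results <- list()
  if (mode %in% c("homology", "homology_then_fold")) {
    templates <- load_records(config$templates, read_xfasta)
    if (is.null(templates) || nrow(templates) == 0)
      stopf("run_pipeline: structure mode '%s' needs templates", mode)
    results <- lapply(seq_len(nrow(its2)), function(i)
      select_best_template(its2$seq[i], templates, target_id = its2$id[i]))
    fh <- filter_by_homology(results, config$min_transfer_percent)
    for (r in results) {
      k <- match(r$id, manifest$id)
      manifest$template[k] <- r$template_name
      manifest$transfer_percent[k] <- r$transfer_percent
    }
    if (length(fh$discarded) > 0)
      drop(vapply(fh$discarded, `[[`, character(1), "id"),
           "low_structural_homology")
    results <- fh$kept
    if (mode == "homology_then_fold") {
      # individualize each homologous helix by constrained folding within
      # the modeled scaffold (ring stays unpaired, helices stay separate)
      results <- lapply(results, function(r) {
        r$structure <- refold_helices(r$seq, r$structure)
        r
      })
    }
  } else {
    results <- lapply(seq_len(nrow(its2)), function(i) {
      forb <- config$constraints[[its2$id[i]]]
      if (is.null(forb)) forb <- integer(0)
      list(id = its2$id[i], seq = its2$seq[i],
           structure = constrained_fold(its2$seq[i], forbidden = forb))
    })
  }
  note("structure_filter")

  pairs <- data.frame(
    id = vapply(results, `[[`, character(1), "id"),
    seq = vapply(results, `[[`, character(1), "seq"),
    structure = vapply(results, `[[`, character(1), "structure"),
    stringsAsFactors = FALSE)

  finish <- function(aborted, encoded = NULL, alignment = NULL,
                     trees = NULL) {
    cdf <- do.call(rbind, lapply(counts, function(x)
      data.frame(stage = x[["stage"]], kept = as.integer(x[["kept"]]),
                 stringsAsFactors = FALSE)))
    out <- list(manifest = manifest, aborted = aborted, pairs = pairs,
                encoded = encoded, alignment = alignment, trees = trees,
                counts = cdf)
    if (!is.null(config$out_dir)) write_run_artifacts(out, config)
    out
  }

  if (sum(manifest$kept) < config$min_taxa) {
    warning(sprintf("pipeline aborted: only %d records survived filtering",
                    sum(manifest$kept)), call. = FALSE)
    return(finish(aborted = TRUE))
  }

  encoded <- encode_pairs(pairs)
  alignment <- progressive_align(encoded, config$scoring)
  trees <- list()
  for (method in config$tree_methods) {
    tree <- switch(method,
      nj = neighbor_joining(dist_matrix(alignment, "jc12")),
      mp = mp_search(alignment)$tree,
      ml = ml_search(alignment, config$model)$tree)
    if (!is.null(config$outgroup) &&
        length(intersect(config$outgroup, tree$tip.label)) > 0)
      tree <- root_with_outgroup(tree,
                                 intersect(config$outgroup, tree$tip.label))
    if (config$bootstrap_B >= 1) {
      reps <- bootstrap_trees(alignment, method = method,
                              B = config$bootstrap_B,
                              seed = config$seed + match(method,
                                                         c("nj", "mp", "ml")),
                              model = config$model)
      tree <- map_support(tree, reps)
    }
    trees[[method]] <- tree
  }
  finish(aborted = FALSE, encoded = encoded, alignment = alignment,
         trees = trees)
}

write_run_artifacts <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  utils::write.table(result$manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$counts, p("stage_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$pairs) && nrow(result$pairs) > 0)
    write_xfasta(result$pairs, p("structures.xfasta"))
  if (!result$aborted) {
    write_encoded_fasta(result$encoded, p("encoded.fasta"))
    write_encoded_fasta(result$alignment, p("alignment.encoded.fasta"))
    dir.create(p("trees"), showWarnings = FALSE)
    for (method in names(result$trees))
      write_newick(result$trees[[method]], p("trees", paste0(method, ".nwk")))
  }
  lines <- c("ssphylo run summary",
             sprintf("structure mode: %s", config$structure_mode),
             sprintf("tree methods: %s",
                     paste(config$tree_methods, collapse = ", ")),
             sprintf("bootstrap replicates: %d", config$bootstrap_B),
             sprintf("seed: %d", config$seed),
             apply(result$counts, 1, function(r)
               sprintf("stage %-20s kept %s", r[["stage"]], r[["kept"]])))
  writeLines(lines, p("summary.txt"))
  invisible(config$out_dir)
}

# degap alignment rows for decoding back to sequence + structure
gsub_rows <- function(alignment) {
  data.frame(id = alignment$id,
             symbols = gsub("-", "", alignment$symbols, fixed = TRUE),
             stringsAsFactors = FALSE)
}
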