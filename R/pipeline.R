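#' Build a pipeline configuration
#'
#' Collects input paths (or in-memory records), stage toggles and every
#' module threshold into one validated object; the configuration is
#' serialised verbatim into the report bundle so outputs are reproducible
#' from the bundle alone.
#'
#' @param inputs Character vector of annotation file paths, or a named list
#'   of `GenomeRecord`s.
#' @param out_dir Output directory for the report bundle.
#' @param fmt Annotation format of file inputs (`"genbank"` or `"gff3"`).
#' @param stages Character vector of stages to run, a subset of
#'   `c("stats", "skew", "codon", "compare", "duplication", "synteny")`.
#' @param min_aa,spacer_window Annotation-scan thresholds (recorded for
#'   provenance; deposited features are used for statistics).
#' @param skew_window,skew_step GC-skew windowing.
#' @param max_evalue Cross-genome homolog E-value cut-off.
#' @param dup_max_evalue Within-genome duplication candidate cut-off.
#' @param nt_min_identity,nt_min_coverage Nucleotide significance profile for
#'   duplication-vs-convergence calls.
#' @param synteny_max_gap Maximum intervening genes when chaining synteny.
#' @param trna_min_coverage,trna_min_identity tRNA homology thresholds.
#' @param seed Seed recorded for any sampling stage.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(inputs, out_dir,
                            fmt = "genbank",
                            stages = c("stats", "skew", "codon", "compare",
                                       "duplication", "synteny"),
                            min_aa = 30L, spacer_window = c(4L, 18L),
                            skew_window = 1000L, skew_step = 500L,
                            max_evalue = 1e-6, dup_max_evalue = 1e-3,
                            nt_min_identity = 65, nt_min_coverage = 50,
                            synteny_max_gap = 3L,
                            trna_min_coverage = 50, trna_min_identity = 70,
                            seed = 1L) {
  known <- c("stats", "skew", "codon", "compare", "duplication", "synteny")
  bad <- setdiff(stages, known)
  if (length(bad)) stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  if (is.character(inputs)) {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing)) stop(sprintf("missing input(s): %s", paste(missing, collapse = ", ")))
  }
  structure(list(
    inputs = inputs, out_dir = out_dir, fmt = fmt, stages = stages,
    min_aa = min_aa, spacer_window = spacer_window,
    skew_window = skew_window, skew_step = skew_step,
    max_evalue = max_evalue, dup_max_evalue = dup_max_evalue,
    nt_min_identity = nt_min_identity, nt_min_coverage = nt_min_coverage,
    synteny_max_gap = synteny_max_gap,
    trna_min_coverage = trna_min_coverage, trna_min_identity = trna_min_identity,
    seed = seed
  ), class = "PipelineConfig")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' Lines are `key = value`; `#` starts a comment. `inputs` and `stages` are
#' comma-separated. Unknown keys raise an error before any computation.
#'
#' @param path Config file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  known <- setdiff(names(formals(pipeline_config)), c("inputs", "out_dir"))
  bad <- setdiff(keys, c(known, "inputs", "out_dir"))
  if (length(bad)) stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    args[[keys[i]]] <- switch(keys[i],
      inputs = , stages = trimws(strsplit(v, ",")[[1]]),
      fmt = , out_dir = v,
      spacer_window = as.integer(trimws(strsplit(v, ",")[[1]])),
      as.numeric(v)
    )
  }
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(pipeline_config, args)
}

.write_tsv <- function(df, path, thresholds = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(thresholds)) {
    writeLines(paste0("# ", paste(names(thresholds), unlist(thresholds),
                                  sep = "=", collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full comparative-genomics pipeline
#'
#' Executes the enabled stages over one or more annotated genomes and writes
#' a TSV + JSON report bundle: per-genome annotation statistics, skew profile
#' with origin/terminus prediction, codon usage and tRNA optimality,
#' pairwise homolog tables with a presence/absence matrix, duplication and
#' split calls, and synteny blocks. Every TSV carries the thresholds used in
#' a `#` header line; `summary.json` embeds the configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list. The bundle is marked `partial` with
#'   the failing stage named if any stage errors.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- if (is.character(config$inputs)) {
    recs <- lapply(config$inputs, read_annotations, fmt = config$fmt)
    names(recs) <- vapply(recs, `[[`, character(1), "id")
    recs
  } else config$inputs
  summary <- list(config = config[setdiff(names(config), "inputs")],
                  genomes = names(records), status = "ok", stages = list())
  fail <- function(stage, e) {
    summary$status <<- "partial"
    summary$stages[[stage]] <<- paste("ERROR:", conditionMessage(e))
  }

  if ("stats" %in% config$stages) tryCatch({
    rows <- lapply(names(records), function(nm) {
      st <- genome_stats(records[[nm]])
      data.frame(genome = nm, length_bp = st$length_bp,
                 gc_percent = round(st$gc_percent, 2), n_cds = st$n_cds,
                 gene_density = st$gene_density,
                 coding_percent = round(st$coding_percent, 1),
                 avg_product_aa = round(st$avg_product_aa, 1),
                 min_product_aa = st$min_product_aa,
                 max_product_aa = st$max_product_aa,
                 n_trna = st$n_trna, malformed = st$malformed,
                 stringsAsFactors = FALSE)
    })
    .write_tsv(do.call(rbind, rows), file.path(config$out_dir, "stats.tsv"))
    summary$stages$stats <- "ok"
  }, error = function(e) fail("stats", e))

  if ("skew" %in% config$stages) tryCatch({
    oriter <- list()
    for (nm in names(records)) {
      prof <- gc_skew(records[[nm]], window = config$skew_window,
                      step = config$skew_step)
      .write_tsv(data.frame(position = prof$positions,
                            window_skew = round(prof$skew, 5),
                            cumulative = prof$cumulative[prof$positions]),
                 file.path(config$out_dir, paste0("skew_", nm, ".tsv")),
                 list(window = prof$window, step = prof$step))
      oriter[[nm]] <- predict_ori_ter(prof)
    }
    summary$stages$skew <- oriter
  }, error = function(e) fail("skew", e))

  if ("codon" %in% config$stages) tryCatch({
    for (nm in names(records)) {
      rec <- records[[nm]]
      usage <- codon_usage(cds_sequences(rec)$cds)
      gc11 <- genetic_code_11()
      .write_tsv(data.frame(codon = names(usage$counts),
                            amino_acid = unname(gc11[names(usage$counts)]),
                            count = usage$counts,
                            per_thousand = round(usage$per_thousand, 2)),
                 file.path(config$out_dir, paste0("codon_usage_", nm, ".tsv")))
      tr <- rec$features[rec$features$kind == "tRNA", , drop = FALSE]
      if (nrow(tr) > 0L && all(!is.na(tr$anticodon))) {
        rep <- trna_optimality(
          data.frame(locus_tag = tr$locus_tag, amino_acid = tr$amino_acid,
                     anticodon = tr$anticodon, stringsAsFactors = FALSE),
          optimal_codons(usage))
        .write_tsv(rep$per_trna,
                   file.path(config$out_dir, paste0("trna_optimality_", nm, ".tsv")))
        summary$stages$codon[[nm]] <- list(
          total_codons = usage$total_codons,
          n_optimal_trnas = rep$n_optimal_trnas, n_trnas = rep$n_trnas,
          n_a_ending = rep$n_a_ending)
      } else {
        summary$stages$codon[[nm]] <- list(total_codons = usage$total_codons)
      }
    }
  }, error = function(e) fail("codon", e))

  proteomes <- NULL
  if (any(c("compare", "synteny") %in% config$stages) && length(records) >= 2L) {
    proteomes <- lapply(records, function(r) cds_sequences(r)$protein)
  }

  if ("compare" %in% config$stages && length(records) >= 2L) tryCatch({
    cg <- core_genome(proteomes, max_evalue = config$max_evalue)
    for (i in names(records)) for (j in names(records)) {
      if (i == j) next
      ht <- find_homologs(proteomes[[i]], proteomes[[j]],
                          max_evalue = config$max_evalue)
      .write_tsv(ht, file.path(config$out_dir,
                               sprintf("homologs_%s_vs_%s.tsv", i, j)),
                 list(max_evalue = config$max_evalue))
    }
    pm <- data.frame(gene = rownames(cg$presence), cg$presence + 0L,
                     check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv(pm, file.path(config$out_dir, "presence_absence.tsv"),
               list(max_evalue = config$max_evalue, reference = cg$reference))
    summary$stages$compare <- list(
      core_size = length(cg$core),
      shared_counts = cg$shared_counts, max_identity = round(cg$max_identity, 1))
  }, error = function(e) fail("compare", e))

  if ("duplication" %in% config$stages) tryCatch({
    for (nm in names(records)) {
      calls <- find_duplications(records[[nm]], max_evalue = config$dup_max_evalue)
      calls <- classify_duplication(records[[nm]], calls,
                                    nt_min_identity = config$nt_min_identity,
                                    nt_min_coverage = config$nt_min_coverage)
      .write_tsv(calls, file.path(config$out_dir, paste0("duplications_", nm, ".tsv")),
                 list(dup_max_evalue = config$dup_max_evalue,
                      nt_min_identity = config$nt_min_identity,
                      nt_min_coverage = config$nt_min_coverage))
      summary$stages$duplication[[nm]] <- table(calls$verdict)
    }
  }, error = function(e) fail("duplication", e))

  if ("synteny" %in% config$stages && length(records) >= 2L) tryCatch({
    nms <- names(records)
    rows <- list()
    for (k in seq_len(length(nms) - 1L)) {
      a <- nms[k]; b <- nms[k + 1L]
      pairs <- homolog_pairs_for_synteny(records[[a]], records[[b]],
                                         max_evalue = config$max_evalue)
      sb <- synteny_blocks(pairs, max_gap = config$synteny_max_gap)
      for (bi in seq_along(sb$blocks)) {
        blk <- sb$blocks[[bi]]
        rows[[length(rows) + 1L]] <- data.frame(
          genome_a = a, genome_b = b, block = bi,
          orientation = attr(blk, "orientation"),
          n_genes = nrow(blk),
          genes = paste(blk$query, collapse = ","), stringsAsFactors = FALSE)
      }
      summary$stages$synteny[[paste(a, b, sep = "|")]] <- list(
        n_blocks = length(sb$blocks), n_relocated = nrow(sb$relocated))
    }
    if (length(rows)) {
      .write_tsv(do.call(rbind, rows), file.path(config$out_dir, "synteny.tsv"),
                 list(max_gap = config$synteny_max_gap))
    }
  }, error = function(e) fail("synteny", e))

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(summary)
}
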