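# End-to-end orchestration: annotate -> classify -> type -> cluster ->
# express -> topology, each stage a package function runnable standalone on
# the previous stage's files. Every parameter is echoed into a run manifest
# together with output checksums, and reruns with an identical config
# reproduce byte-identical outputs.

#' Default pipeline configuration
#'
#' Stage parameters default to the module defaults; input paths default to
#' NULL and stages whose inputs are absent are skipped.
#'
#' @export
default_pipeline_config <- function() {
  list(
    genome_fasta = NULL, gff3 = NULL,
    anchors_fasta = NULL, anchors_tsv = NULL,
    counts_tsv = NULL, gene_lengths_tsv = NULL, library_sizes_tsv = NULL,
    library_groups_yaml = NULL,
    proteins_fasta = NULL,
    outdir = "gr_run", seed = 1,
    distance_model = "poisson", max_distance = 10,
    bootstrap_replicates = 0,
    require_start_met = TRUE,
    type2_min_len = 400, type3_min_len = 200, type3_max_len = 360,
    array_max_gap = 1e5, array_min_size = 3,
    rpkm_cutoff = 1,
    topology_window = 19, topology_threshold = 1.6,
    min_tm_len = 15, topology_merge_gap = 4)
}

merge_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

#' Run the repertoire pipeline
#'
#' @param config Named list of config overrides (see
#'   [default_pipeline_config()]) or a path to a YAML file holding them.
#'   Unknown keys are rejected.
#' @return Invisibly, a list with the per-stage results and the output
#'   directory. On a stage failure a `FAILED` marker naming the stage is
#'   left in the run directory and the error is rethrown.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_pipeline_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(outdir = outdir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  unlink(file.path(outdir, "FAILED"))

  ## annotate -------------------------------------------------------------
  models <- NULL
  if (!is.null(cfg$genome_fasta) && !is.null(cfg$gff3)) {
    models <- stage("annotate", {
      scaffolds <- read_fasta(cfg$genome_fasta, "dna")
      m <- suppressWarnings(read_gff3(cfg$gff3, scaffolds))
      tab <- gene_model_table(m)
      tab$pseudogene <- vapply(m, detect_pseudogene, logical(1))
      tab$partial <- vapply(m, function(x)
        detect_partial(x$protein, x$has_terminal_stop,
                       cfg$require_start_met), character(1))
      write_tsv(tab, file.path(outdir, "gene_models.tsv"))
      res$gene_models <- tab
      m
    })
  } else if (!is.null(cfg$gff3) || !is.null(cfg$genome_fasta)) {
    stage("annotate", stop("both genome_fasta and gff3 are required"))
  }

  ## classify -------------------------------------------------------------
  assignments <- NULL
  if (!is.null(models) && !is.null(cfg$anchors_fasta)) {
    assignments <- stage("classify", {
      if (is.null(cfg$anchors_tsv))
        stop("anchors_tsv (anchor_id, subfamily) is required with anchors_fasta")
      anchors_fa <- read_fasta(cfg$anchors_fasta, "protein")
      anchor_tab <- read_tsv(cfg$anchors_tsv)
      anchors <- setNames(anchor_tab$subfamily, anchor_tab$anchor_id)
      gene_seqs <- tree_proteins(models)
      if (length(gene_seqs) == 0) {
        asn <- data.frame(gene_id = character(0), subfamily = character(0),
                          anchor_support = character(0),
                          ambiguous = logical(0), stringsAsFactors = FALSE)
      } else {
        all_seqs <- c(gene_seqs, setNames(as.character(anchors_fa),
                                          names(anchors_fa)))
        msa <- align_msa(all_seqs)
        if (cfg$bootstrap_replicates > 0) {
          bs <- bootstrap_support(msa, cfg$bootstrap_replicates,
                                  seed = cfg$seed,
                                  model = cfg$distance_model,
                                  max_distance = cfg$max_distance)
          tree <- bs$tree
        } else {
          tree <- build_nj_tree(msa_distances(msa, cfg$distance_model,
                                              cfg$max_distance))
        }
        ape::write.tree(tree, file.path(outdir, "tree.nwk"))
        asn <- assign_subfamilies(tree, anchors)
        res$tree <- tree
      }
      write_tsv(asn, file.path(outdir, "assignments.tsv"))
      asn
    })
  }

  ## type -----------------------------------------------------------------
  if (!is.null(models)) {
    stage("type", {
      tab <- res$gene_models
      tab$subfamily <- if (!is.null(assignments))
        assignments$subfamily[match(tab$gene_id, assignments$gene_id)]
      else rep(NA_character_, nrow(tab))
      tab$subfamily[is.na(tab$subfamily)] <- "unassigned"
      # genes dropped from the tree (e.g. too-short pseudogene fragments)
      # keep their structural flags but stay untyped
      cls <- classify_repertoire(
        tab, type2_min_len = cfg$type2_min_len,
        type3_min_len = cfg$type3_min_len, type3_max_len = cfg$type3_max_len)
      per_gene <- cls[, c("gene_id", "scaffold", "start", "end", "strand",
                          "subfamily", "bitter_type", "length_aa",
                          "exon_count", "pseudogene", "partial")]
      summary <- summarize_repertoire(per_gene)
      write_repertoire_tables(per_gene, summary, outdir)
      write_tsv(table1_row(summary), file.path(outdir, "table1_row.tsv"))
      res$per_gene <- per_gene
      res$summary <- summary
    })
  }

  ## cluster --------------------------------------------------------------
  if (!is.null(res$per_gene)) {
    stage("cluster", {
      pg <- res$per_gene
      arrays <- do.call(rbind, lapply(c("type1", "type2", "type3"),
        function(t) detect_tandem_arrays(pg, cfg$array_max_gap,
                                         cfg$array_min_size, t)))
      if (is.null(arrays) || !nrow(arrays))
        arrays <- detect_tandem_arrays(pg[0, ], cfg$array_max_gap,
                                       cfg$array_min_size)
      write_tsv(arrays, file.path(outdir, "arrays.tsv"))
      res$arrays <- arrays
    })
  }

  ## express --------------------------------------------------------------
  if (!is.null(cfg$counts_tsv)) {
    stage("express", {
      if (is.null(cfg$gene_lengths_tsv) || is.null(cfg$library_sizes_tsv))
        stop("counts_tsv needs gene_lengths_tsv and library_sizes_tsv")
      cdf <- read_tsv(cfg$counts_tsv)
      cts <- as.matrix(cdf[, -1, drop = FALSE])
      storage.mode(cts) <- "integer"
      rownames(cts) <- cdf[[1]]
      rn <- read_tsv(cfg$gene_lengths_tsv)
      gl <- setNames(rn[[2]], rn[[1]])
      ls_tab <- read_tsv(cfg$library_sizes_tsv)
      ls <- setNames(ls_tab[[2]], ls_tab[[1]])
      ab <- relative_abundance(cts, gl, ls)
      pres <- call_presence(ab, cfg$rpkm_cutoff)
      write_tsv(data.frame(gene_id = rownames(ab), round(ab, 4),
                           check.names = FALSE),
                file.path(outdir, "abundance.tsv"))
      write_tsv(data.frame(gene_id = rownames(pres), pres,
                           check.names = FALSE),
                file.path(outdir, "presence.tsv"))
      if (!is.null(cfg$library_groups_yaml)) {
        groups <- yaml::read_yaml(cfg$library_groups_yaml)
        smry <- presence_summary(pres, groups)
        write_tsv(smry$group_counts,
                  file.path(outdir, "expression_groups.tsv"))
        write_tsv(smry$gene_breadth, file.path(outdir, "gene_breadth.tsv"))
        res$expression <- smry
      }
      res$presence <- pres
    })
  }

  ## topology -------------------------------------------------------------
  topo_seqs <- NULL
  if (!is.null(cfg$proteins_fasta)) {
    topo_seqs <- as.character(read_fasta(cfg$proteins_fasta, "protein"))
  } else if (!is.null(models)) {
    ok <- !vapply(models, `[[`, logical(1), "internal_stop")
    topo_seqs <- as.character(gene_model_proteins(models[ok]))
  }
  if (!is.null(topo_seqs)) {
    stage("topology", {
      topo_seqs <- topo_seqs[nchar(topo_seqs) >= cfg$topology_window]
      topo <- topology_table(topo_seqs, window = cfg$topology_window,
                             threshold = cfg$topology_threshold,
                             min_tm_len = cfg$min_tm_len,
                             merge_gap = cfg$topology_merge_gap)
      write_tsv(topo, file.path(outdir, "topology.tsv"))
      res$topology <- topo
    })
  }

  ## manifest -------------------------------------------------------------
  outputs <- sort(setdiff(list.files(outdir), "manifest.yaml"))
  sums <- tools::md5sum(file.path(outdir, outputs))
  yaml::write_yaml(list(
    config = cfg[order(names(cfg))],
    outputs = as.list(setNames(unname(sums), outputs))),
    file.path(outdir, "manifest.yaml"))
  invisible(res)
}
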