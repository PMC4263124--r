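#' Default pipeline configuration
#'
#' Returns the resolved default configuration of [run_pipeline()]: stage
#' toggles and per-stage parameter blocks. Unknown keys in a user
#' configuration are rejected.
#'
#' @return Nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, bin = TRUE, popsize = TRUE,
                  express = TRUE, variants = TRUE, nsi = TRUE,
                  ecology = TRUE),
    community = list(preset = "default"),
    bin = list(k = NULL, perplexity = 30, min_length = 500,
               round2_min_length = 1000, pseudocount = 1,
               min_posterior = 0.5, iterate = TRUE, delta_bic = 10,
               k_max = 10),
    popsize = list(mode = "relative"),
    express = list(factor = 50),
    variants = list(min_depth = 10),
    ecology = list(depth = 6359, reps = 10)
  )
}

merge_config <- function(user, defaults = default_pipeline_config()) {
  if (is.null(user)) return(defaults)
  check <- function(u, d, path = "") {
    extra <- setdiff(names(u), names(d))
    if (length(extra) && path %in% c("", "stages", "bin", "popsize",
                                     "express", "variants", "ecology"))
      stop("unknown configuration key(s): ",
           paste0(path, if (nzchar(path)) "$", extra, collapse = ", "))
  }
  check(user, defaults)
  for (blk in intersect(names(user), names(defaults))) {
    if (is.list(defaults[[blk]]) && is.list(user[[blk]])) {
      check(user[[blk]], defaults[[blk]], blk)
      defaults[[blk]] <- modifyList(defaults[[blk]], user[[blk]])
    } else {
      defaults[[blk]] <- user[[blk]]
    }
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' YAML configuration merged over [default_pipeline_config()]; unknown keys
#' are rejected.
#'
#' @param path YAML file.
#' @return Resolved configuration list.
#' @export
read_config <- function(path) merge_config(yaml::read_yaml(path))

community_from_config <- function(cfg, seed) {
  cc <- cfg$community
  if (!is.null(cc$preset) && cc$preset == "default")
    return(default_community_spec(rng_seed = seed))
  pops <- lapply(cc$populations, function(p) do.call(population_spec, p))
  community_spec(pops,
                 total_metag_reads = cc$total_metag_reads %||% 2e6,
                 total_metat_reads = cc$total_metat_reads %||% 2e6,
                 read_length = cc$read_length %||% 100,
                 contig_length_law = cc$contig_length_law %||%
                   list(dist = "loguniform", min = 1000, max = 20000),
                 rng_seed = seed)
}

require_inputs <- function(out_dir, files, stage) {
  missing <- files[!file.exists(file.path(out_dir, files))]
  if (length(missing))
    stop("stage '", stage, "' is missing upstream output(s): ",
         paste(missing, collapse = ", "))
}

#' Run the full population-resolved omics pipeline
#'
#' Executes the enabled stages in dependency order - simulate, bin, popsize,
#' express, variants, nsi, ecology - reading and writing the standard file
#' formats in `out_dir`. A resolved copy of the configuration and a run
#' manifest (per-stage parameters, output file digests and warning counts)
#' are written alongside the outputs. Identical configuration and seed
#' reproduce byte-identical outputs.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   YAML file path.
#' @param out_dir Output directory.
#' @param seed Root seed; overrides `config$seed` when given.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_config(config)
         else merge_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  manifest <- list()
  p <- function(...) file.path(out_dir, ...)
  run_stage <- function(name, params, outputs, fn) {
    warns <- character(0)
    withCallingHandlers(fn(), warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    md5 <- tools::md5sum(p(outputs))
    names(md5) <- outputs
    manifest[[name]] <<- list(
      stage = name, params = params, outputs = as.list(md5),
      n_warnings = length(warns), warnings = warns
    )
  }

  if (isTRUE(cfg$stages$simulate)) {
    outs <- c("contigs.fasta", "genes.gff3", "metag_counts.tsv",
              "metat_counts.tsv", "depth.tsv", "protein_evidence.tsv",
              "annotations.tsv", "markers.tsv", "abundance.tsv", "lipids.tsv")
    run_stage("simulate", cfg$community, outs, function() {
      spec <- community_from_config(cfg, cfg$seed)
      write_community(simulate_community(spec), out_dir)
    })
  }

  if (isTRUE(cfg$stages$bin)) {
    require_inputs(out_dir, c("contigs.fasta", "metag_counts.tsv",
                              "depth.tsv"), "bin")
    run_stage("bin", cfg$bin, c("signatures.tsv", "embedding.tsv",
                                "bins.tsv"), function() {
      seqs <- read_fasta(p("contigs.fasta"))
      counts <- read_tsv(p("metag_counts.tsv"))
      depth <- read_tsv(p("depth.tsv"))
      k <- cfg$bin[["k", exact = TRUE]]
      if (is.null(k) && file.exists(p("truth", "abundance_truth.tsv")))
        k <- nrow(read_tsv(p("truth", "abundance_truth.tsv")))
      res <- bin_contigs(
        seqs, k = if (identical(k, "bic")) NULL else k,
        counts = counts,
        depths = setNames(depth$depth_g, depth$id),
        min_length = cfg$bin$min_length,
        round2_min_length = cfg$bin$round2_min_length,
        iterate = cfg$bin$iterate, perplexity = cfg$bin$perplexity,
        seed = cfg$seed, pseudocount = cfg$bin$pseudocount,
        min_posterior = cfg$bin$min_posterior, k_max = cfg$bin$k_max,
        delta_bic = cfg$bin$delta_bic)
      sig <- res$signatures
      write_tsv(data.frame(contig = sig$contig_id, length = sig$length,
                           gc = sig$gc, round(sig$clr, 6),
                           check.names = FALSE, stringsAsFactors = FALSE),
                p("signatures.tsv"),
                meta = list(transform = "centred log-ratio",
                            pseudocount = cfg$bin$pseudocount))
      write_tsv(res$embedding, p("embedding.tsv"))
      write_tsv(res$assignments, p("bins.tsv"))
    })
  }

  if (isTRUE(cfg$stages$popsize)) {
    require_inputs(out_dir, c("bins.tsv", "metag_counts.tsv"), "popsize")
    run_stage("popsize", cfg$popsize, "population_profile.tsv", function() {
      bins <- read_tsv(p("bins.tsv"))
      counts <- read_tsv(p("metag_counts.tsv"))
      counts <- counts[counts$id %in% bins$contig_id, , drop = FALSE]
      rec <- recruit_reads(bins, counts)
      binned <- bins[bins$cg_id != "unbinned", , drop = FALSE]
      l_i <- tapply(counts$length[match(binned$contig_id, counts$id)],
                    binned$cg_id, sum)
      prof <- data.frame(cg_id = names(rec$c_i),
                         l_i = as.numeric(l_i[names(rec$c_i)]),
                         c_i = as.numeric(rec$c_i),
                         stringsAsFactors = FALSE)
      prof <- population_size(prof, mode = cfg$popsize$mode)
      read_length <- cfg$community$read_length %||% 100
      prof$mean_coverage <- prof$c_i * read_length / prof$l_i
      write_tsv(prof, p("population_profile.tsv"),
                meta = list(N_mode = cfg$popsize$mode,
                            units = "l_i bases; c_i mapped reads"))
    })
  }

  if (isTRUE(cfg$stages$express)) {
    require_inputs(out_dir, c("genes.gff3", "bins.tsv", "metat_counts.tsv",
                              "population_profile.tsv"), "express")
    run_stage("express", cfg$express,
              c("expression.tsv", "expressed_fraction.tsv"), function() {
      genes <- read_gff3(p("genes.gff3"))
      bins <- read_tsv(p("bins.tsv"))
      metat <- read_tsv(p("metat_counts.tsv"))
      prof <- read_tsv(p("population_profile.tsv"))
      expr <- expression_table(genes, bins, metat, prof,
                               factor = cfg$express$factor)
      write_tsv(expr, p("expression.tsv"),
                meta = list(rule = paste0("expressed iff metaT FPKM >= ",
                                          cfg$express$factor, " * N_i"),
                            N_mode = attr(prof, "mode") %||% "relative"))
      keep <- !is.na(expr$cg_id) & expr$cg_id != "unbinned"
      frac <- tapply(expr$expressed[keep], expr$cg_id[keep],
                     expressed_fraction)
      write_tsv(data.frame(cg_id = names(frac),
                           pct_expressed = as.numeric(frac),
                           stringsAsFactors = FALSE),
                p("expressed_fraction.tsv"),
                meta = list(units = "percent of genes"))
      if (file.exists(p("annotations.tsv"))) {
        ann <- read_tsv(p("annotations.tsv"))
        cogs <- ann$cog[match(expr$gene_id, ann$gene_id)]
        cogs[is.na(cogs)] <- ""
        profs <- lapply(split(cogs[keep], expr$cg_id[keep]), cog_profile)
        cp <- do.call(rbind, lapply(names(profs), function(cg)
          data.frame(cg_id = cg, category = names(profs[[cg]]$counts),
                     count = profs[[cg]]$counts,
                     normalized = as.numeric(profs[[cg]]$normalized),
                     stringsAsFactors = FALSE)))
        rownames(cp) <- NULL
        write_tsv(cp, p("cog_profile.tsv"),
                  meta = list(normalized = "count / CG gene total"))
      }
    })
  }

  if (isTRUE(cfg$stages$variants)) {
    vcfs <- list.files(out_dir, pattern = "^caller_.*\\.vcf$",
                       full.names = TRUE)
    if (length(vcfs) < 2)
      stop("stage 'variants' needs at least two caller_*.vcf inputs")
    require_inputs(out_dir, c("population_profile.tsv", "bins.tsv",
                              "genes.gff3"), "variants")
    run_stage("variants", cfg$variants,
              c("variants_intersection.vcf", "variant_density.tsv",
                "per_gene_snps.tsv"), function() {
      sets <- lapply(vcfs, parse_vcf)
      cons <- depth_filter(intersect_callsets(sets),
                           min_depth = cfg$variants$min_depth)
      write_vcf(cons, p("variants_intersection.vcf"),
                source = "popomics-intersection")
      bins <- read_tsv(p("bins.tsv"))
      prof <- read_tsv(p("population_profile.tsv"))
      dens <- variant_summary(cons, bins, prof)
      write_tsv(dens, p("variant_density.tsv"),
                meta = list(normalized_density = "snp_per_kb / N_i"))
      genes <- read_gff3(p("genes.gff3"))
      pg <- per_gene_variant_counts(cons, genes)
      write_tsv(pg$per_gene, p("per_gene_snps.tsv"),
                meta = list(intergenic = pg$intergenic))
    })
  }

  if (isTRUE(cfg$stages$nsi)) {
    require_inputs(out_dir, "protein_evidence.tsv", "nsi")
    run_stage("nsi", list(), "nsi.tsv", function() {
      ev <- read_tsv(p("protein_evidence.tsv"))
      write_tsv(nsi_table(ev), p("nsi.tsv"),
                meta = list(nsi = "si_raw / (length_aa * total si)",
                            log2_nsi = "log2(nsi)"))
    })
  }

  if (isTRUE(cfg$stages$ecology)) {
    require_inputs(out_dir, c("abundance.tsv", "lipids.tsv"), "ecology")
    run_stage("ecology", cfg$ecology,
              c("diversity.tsv", "ratios.tsv", "correlations.tsv"),
              function() {
      ab <- read_tsv(p("abundance.tsv"), check.names = FALSE)
      m <- as.matrix(ab[, -1, drop = FALSE])
      rownames(m) <- ab$taxon
      depth <- min(cfg$ecology$depth, min(colSums(m)))
      div <- diversity_indices(m, depth = depth, reps = cfg$ecology$reps,
                               seed = cfg$seed)
      write_tsv(div, p("diversity.tsv"),
                meta = list(simpson_form = "gini_simpson (1 - sum p^2)",
                            depth = depth, reps = cfg$ecology$reps))
      lip <- accumulation_ratio(read_tsv(p("lipids.tsv")))
      write_tsv(lip, p("ratios.tsv"),
                meta = list(ratio = "intracellular / extracellular"))
      write_tsv(taxon_lipid_correlations(m, lip), p("correlations.tsv"),
                meta = list(method = "Spearman, average-tie ranks"))
    })
  }

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
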