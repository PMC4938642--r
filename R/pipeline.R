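#' Read a pipeline configuration from YAML
#'
#' The configuration is a single YAML document with optional per-stage
#' blocks (`sim`, `chip`, `methylome`, `metaplot`), a global `seed`, an
#' `outdir`, and an `inputs` block pointing at pre-existing files when the
#' `simulate` stage is not run. Unspecified values fall back to package
#' defaults.
#'
#' @param path YAML file.
#' @return A named list usable as the `config` of [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

default_pipeline_config <- function() {
  list(seed = 1L, outdir = ".",
       mito_name = "mito",
       mutant_domain_meth_freq = 0.55,
       sim = list(),
       inputs = list(),
       chip = list(window_bp = 1000L),
       methylome = list(min_coverage = 3L, alpha = 0.05,
                        dmr_window_bp = 1000L, dmr_step_bp = 100L,
                        dmr_min_diff = 20, dmr_alpha = 0.05,
                        dmr_merge_gap_bp = 500L, dmr_min_sites = 5L,
                        track_window_bp = 10000L),
       metaplot = list(flank_bp = 1000L, bin_bp = 10L))
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(user[[k]]) && is.list(defaults[[k]])) {
      merge_config(defaults[[k]], user[[k]])
    } else user[[k]]
  }
  defaults
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order. The `simulate`
#' stage generates a complete synthetic experiment (genome, genes,
#' domains, tagged and control ChIP libraries, wild-type-like and
#' mutant-like MNase and bisulfite libraries, the mutant differing only
#' in domain methylation frequency) and writes it to `outdir`; analysis
#' stages (`chip`, `methylome`, `mnase`, `metaplot`) consume either the
#' simulated files or user-supplied paths from `config$inputs`. Every run
#' writes a `manifest.json` with the configuration, the seed, and an MD5
#' checksum per output file, so identical config and seed reproduce
#' byte-identical outputs; a `run.log` records the exact parameter values
#' each stage used. A failed analysis stage is recorded in the manifest
#' and does not abort independent stages.
#'
#' @param config list (see [read_pipeline_config()]) or path to a YAML
#'   file.
#' @param stages subset of
#'   `c("simulate", "chip", "methylome", "mnase", "metaplot")`.
#' @param outdir output directory (overrides `config$outdir`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "chip", "methylome",
                                    "mnase", "metaplot"),
                         outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  out_path <- function(f) file.path(cfg$outdir, f)
  files <- character()
  add_file <- function(p) files <<- c(files, p)
  status <- list()

  # fail early if a requested stage has no resolvable input
  requirements <- list(
    chip = c("genome", "chip_tagged", "chip_control"),
    methylome = c("genome", "domains", "bisulfite_wt", "bisulfite_mut"),
    mnase = c("genome", "genes", "mnase_wt", "mnase_mut"),
    metaplot = c("genome", "genes", "chip_tagged"))
  if (!("simulate" %in% stages)) {
    for (stage in intersect(stages, names(requirements))) {
      missing <- setdiff(requirements[[stage]], names(cfg$inputs))
      if (length(missing)) {
        stop("stage '", stage, "' is missing input '", missing[1L],
             "': run the simulate stage or set inputs$", missing[1L])
      }
    }
  }

  sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  data <- list()

  if ("simulate" %in% stages) {
    note("simulate: seed %d, %d nuclear contigs x %d bp, mito %d bp",
         cfg$seed, sim_cfg$n_nuclear_contigs, sim_cfg$contig_length_bp,
         sim_cfg$mito_length_bp)
    sim <- simulate_genome(sim_cfg)
    data$genome <- sim$genome
    data$genes <- sim$genes
    data$domains <- sim$domains
    add_file(write_genome(sim$genome, out_path("genome.fa")))
    add_file(write_genes(sim$genes, out_path("genes.tsv")))
    add_file(write_intervals(sim$domains, out_path("domains.bed")))
    data$chip_tagged <- simulate_chip(sim$genome, sim$genes, sim_cfg,
                                      tagged = TRUE, seed = cfg$seed + 1L)
    data$chip_control <- simulate_chip(sim$genome, sim$genes, sim_cfg,
                                       tagged = FALSE,
                                       seed = cfg$seed + 2L)
    data$mnase_wt <- simulate_mnase(sim$genome, sim$genes, sim_cfg,
                                    seed = cfg$seed + 3L)
    data$mnase_mut <- simulate_mnase(sim$genome, sim$genes, sim_cfg,
                                     seed = cfg$seed + 4L)
    data$bisulfite_wt <- simulate_bisulfite(sim$genome, sim$domains,
                                            sim_cfg,
                                            seed = cfg$seed + 5L)
    data$bisulfite_mut <- simulate_bisulfite(
      sim$genome, sim$domains, sim_cfg, seed = cfg$seed + 6L,
      domain_meth_freq = cfg$mutant_domain_meth_freq)
    add_file(write_fragments(data$chip_tagged, out_path("chip_tagged.bed")))
    add_file(write_fragments(data$chip_control,
                             out_path("chip_control.bed")))
    add_file(write_fragments(data$mnase_wt, out_path("mnase_wt.bed")))
    add_file(write_fragments(data$mnase_mut, out_path("mnase_mut.bed")))
    add_file(write_cytosine_report(data$bisulfite_wt,
                                   out_path("bisulfite_wt.tsv")))
    add_file(write_cytosine_report(data$bisulfite_mut,
                                   out_path("bisulfite_mut.tsv")))
    note("simulate: wrote genome, annotation, domains, %d+%d ChIP, %d+%d MNase fragments, %d+%d cytosine sites",
         nrow(data$chip_tagged), nrow(data$chip_control),
         nrow(data$mnase_wt), nrow(data$mnase_mut),
         nrow(data$bisulfite_wt), nrow(data$bisulfite_mut))
    status$simulate <- "ok"
  }

  need <- function(name) {
    if (!is.null(data[[name]])) return(data[[name]])
    path <- cfg$inputs[[name]]
    if (is.null(path)) {
      stop("missing input '", name,
           "': run the simulate stage or set inputs$", name,
           call. = FALSE)
    }
    value <- switch(name,
      genome = read_genome(path, cfg$mito_name),
      genes = read_genes(path),
      domains = read_intervals(path),
      bisulfite_wt = ,
      bisulfite_mut = read_cytosine_report(path),
      read_fragments(path))
    data[[name]] <<- value
    value
  }

  run_stage <- function(stage, fun) {
    if (!(stage %in% stages)) return()
    status[[stage]] <<- tryCatch({
      fun()
      "ok"
    }, error = function(e) {
      note("%s: FAILED (%s)", stage, conditionMessage(e))
      paste("failed:", conditionMessage(e))
    })
  }

  run_stage("chip", function() {
    gen <- need("genome")
    wbp <- cfg$chip$window_bp
    for (lib in c("chip_tagged", "chip_control")) {
      frags <- need(lib)
      raw <- window_counts(frags, gen, window_bp = wbp)
      norm <- mito_normalize(raw, gen)
      note("chip: %s, %d fragments, %d windows of %d bp, mitochondrial median %.1f",
           lib, nrow(frags), nrow(raw), wbp, attr(norm, "mito_median"))
      add_file(write_track(raw, out_path(paste0(lib, "_counts.bedgraph"))))
      add_file(write_track(norm,
                           out_path(paste0(lib, "_enrichment.bedgraph"))))
    }
  })

  run_stage("methylome", function() {
    gen <- need("genome")
    mc <- cfg$methylome
    reports <- list(wt = need("bisulfite_wt"), mut = need("bisulfite_mut"))
    calls <- list()
    for (strain in names(reports)) {
      nc <- estimate_nonconversion(reports[[strain]], gen)
      calls[[strain]] <- call_sites(reports[[strain]], nc,
                                    min_coverage = mc$min_coverage,
                                    alpha = mc$alpha)
      note("methylome: %s nonconversion %.4f, min coverage %d, alpha %.2f, %d methylated cytosines",
           strain, nc, mc$min_coverage, mc$alpha,
           count_methylated(calls[[strain]]))
      path <- out_path(paste0("calls_", strain, ".tsv"))
      writeLines(sprintf("# nonconversion_rate=%.6g min_coverage=%d alpha=%g",
                         nc, mc$min_coverage, mc$alpha), path)
      data.table::fwrite(calls[[strain]], path, sep = "\t", append = TRUE,
                         col.names = TRUE)
      add_file(path)
      track <- methylation_track(reports[[strain]], gen,
                                 window_bp = mc$track_window_bp,
                                 min_coverage = mc$min_coverage)
      track$value[is.na(track$value)] <- 0
      add_file(write_track(track,
                           out_path(paste0("methylation_", strain,
                                           "_10kb.bedgraph"))))
    }
    shared <- shared_site_distribution(calls$wt, calls$mut)
    sh_path <- out_path("shared_site_distribution.tsv")
    data.table::fwrite(shared, sh_path, sep = "\t")
    add_file(sh_path)
    dmrs <- find_dmrs(reports$wt, reports$mut, gen,
                      dmr_window_bp = mc$dmr_window_bp,
                      dmr_step_bp = mc$dmr_step_bp,
                      dmr_min_diff = mc$dmr_min_diff,
                      dmr_alpha = mc$dmr_alpha,
                      dmr_merge_gap_bp = mc$dmr_merge_gap_bp,
                      min_coverage = mc$min_coverage,
                      dmr_min_sites = mc$dmr_min_sites)
    note("methylome: %d DMR(s) (window %d, step %d, min diff %g points)",
         nrow(dmrs), mc$dmr_window_bp, mc$dmr_step_bp, mc$dmr_min_diff)
    add_file(write_intervals(dmrs, out_path("dmrs.bed")))
    domains <- need("domains")
    for (strain in names(reports)) {
      dm <- domain_metaplot(reports[[strain]], domains,
                            min_coverage = mc$min_coverage)
      p <- out_path(paste0("domain_metaplot_", strain, ".tsv"))
      data.table::fwrite(dm, p, sep = "\t")
      add_file(p)
    }
  })

  run_stage("mnase", function() {
    gen <- need("genome")
    genes <- need("genes")
    grouping <- assign_quintiles(genes)
    mp <- cfg$metaplot
    stats_rows <- list()
    for (lib in c("mnase_wt", "mnase_mut")) {
      frags <- need(lib)
      dedup <- deduplicate(frags)
      s_raw <- insert_size_stats(frags)
      s_dd <- insert_size_stats(dedup)
      note("mnase: %s insert size %.1f +/- %.1f bp raw (n=%d), %.1f +/- %.1f bp deduplicated (n=%d)",
           lib, s_raw$mean_bp, s_raw$sd_bp, s_raw$n_fragments,
           s_dd$mean_bp, s_dd$sd_bp, s_dd$n_fragments)
      stats_rows[[lib]] <- data.frame(
        library = lib,
        stage = c("raw", "deduplicated"),
        n_fragments = c(s_raw$n_fragments, s_dd$n_fragments),
        mean_bp = c(s_raw$mean_bp, s_dd$mean_bp),
        sd_bp = c(s_raw$sd_bp, s_dd$sd_bp))
      prof <- edge_profile(dedup, genes, gen, grouping = grouping,
                           flank_bp = mp$flank_bp, bin_bp = mp$bin_bp)
      p <- out_path(paste0("edge_profile_", lib, ".tsv"))
      data.table::fwrite(prof, p, sep = "\t")
      add_file(p)
    }
    p <- out_path("insert_size_stats.tsv")
    data.table::fwrite(do.call(rbind, stats_rows), p, sep = "\t")
    add_file(p)
  })

  run_stage("metaplot", function() {
    gen <- need("genome")
    genes <- need("genes")
    frags <- need("chip_tagged")
    mp <- cfg$metaplot
    grouping <- assign_quintiles(genes)
    b <- grouping$boundaries
    note("metaplot: quintile RPKM boundaries %s",
         paste(sprintf("Q%d (%.1f-%.1f)", b$quintile, b$max_rpkm,
                       b$min_rpkm), collapse = "; "))
    signal <- scale_unit_mean(basewise_coverage(frags, gen,
                                                mode = "full_fragment"))
    for (anchor in c("TSS", "TTS")) {
      prof <- gene_metaplot(signal, genes, anchor = anchor,
                            flank_bp = mp$flank_bp, bin_bp = mp$bin_bp,
                            grouping = grouping)
      p <- out_path(paste0("chip_metaplot_",
                           tolower(anchor), ".tsv"))
      data.table::fwrite(prof, p, sep = "\t")
      add_file(p)
    }
    hm <- heatmap_matrix(signal, genes, anchor = "TSS",
                         flank_bp = mp$flank_bp, bin_bp = mp$bin_bp)
    p <- out_path("chip_heatmap_tss.tsv")
    data.table::fwrite(data.frame(gene_id = rownames(hm), hm,
                                  check.names = FALSE),
                       p, sep = "\t")
    add_file(p)
    note("metaplot: %d genes x %d bins, anchor window +/-%d bp, bin %d bp",
         nrow(hm), ncol(hm), mp$flank_bp, mp$bin_bp)
  })

  manifest <- list(
    package = "chromquant",
    version = as.character(utils::packageVersion("chromquant")),
    seed = cfg$seed,
    stages = stages,
    status = status,
    config = cfg,
    outputs = lapply(stats::setNames(files, basename(files)), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  manifest_path <- out_path("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, out_path("run.log"))
  invisible(manifest)
}
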