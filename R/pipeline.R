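# End-to-end orchestration: a single structured (YAML) config drives
# simulate -> profile -> compare -> report, with a manifest recording the
# seed, config hash and every output file. Identical config + seed yields
# byte-identical numeric outputs.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "magvar_out",
    scenario = list(
      n_populations = 4L,
      groups = c("field_A", "field_A", "field_B", "field_B"),
      contig_length = 6000L,
      orf_density = 0.7,
      proportions = c(0.7, 0.3),
      n_snvs = 60L,
      nonsyn_fraction = c(0.25, 0.25, 0.38, 0.38),
      depth = 60,
      read_length = 170L,
      error_rate = 0,
      total_reads = 5e7,
      ani_divergences = c(0, 0.01, 0.02),
      pangenome = list(n_mags = 6L, n_core = 120L, n_accessory = 15L,
                      focal_pair_unique = 40L, enriched_category = "M",
                      enrichment_strength = 0.5, background_frequency = 0.1)
    ),
    thresholds = list(
      min_coverage = 10L, min_departure = 0.05,
      ani_min_identity = 0.7, ani_min_fragment_coverage = 0.7,
      inflation = 2, maxbit = 0.3,
      enrichment_repetitions = 500L, enrichment_sample_size = 100L,
      enrichment_levels = c(0.90, 0.93, 0.99)
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read and validate a pipeline run configuration
#'
#' @param path YAML config file; missing entries fall back to the bundled
#'   demo scenario defaults.
#' @return Validated config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  if (is.null(cfg$seed)) stop("config: seed is mandatory", call. = FALSE)
  if (th$min_departure < 0 || th$min_departure > 1) {
    stop("config: min_departure must be in [0, 1]", call. = FALSE)
  }
  if (th$min_coverage < 1) stop("config: min_coverage must be >= 1", call. = FALSE)
  if (th$maxbit < 0 || th$maxbit > 1) {
    stop("config: maxbit must be in [0, 1]", call. = FALSE)
  }
  if (th$inflation <= 1) stop("config: inflation must exceed 1", call. = FALSE)
  sc <- cfg$scenario
  if (!is.null(sc)) {
    if (abs(sum(sc$proportions) - 1) > 1e-8) {
      stop("config: strain proportions must sum to 1", call. = FALSE)
    }
    if (any(sc$ani_divergences < 0 | sc$ani_divergences > 0.25)) {
      stop("config: ani_divergences must be in [0, 0.25]", call. = FALSE)
    }
  }
  cfg
}

stage_log <- function(stage, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", stage))
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] failed: %s", stage, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

write_tsv <- function(x, path, digits = 6) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) {
    ifelse(is.na(v), NA, format(round(v, digits), trim = TRUE,
                                scientific = FALSE))
  })
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full demo pipeline
#'
#' Simulates the configured strain communities, profiles SNVs/SAAVs per
#' simulated population, writes the per-MAG summary table, compares the
#' log SAAV/SNV ratios between the two configured groups with a Welch
#' t-test, computes an ANI ladder over simulated divergent genome pairs,
#' builds the planted pangenome with its dendrogram, uniquely shared
#' clusters and enrichment table, and writes a manifest.
#'
#' @param config Config list from [read_run_config()], or a YAML path.
#' @param out_dir Output directory (overrides the config entry).
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else {
    validate_config(merge_config(default_config(), config %||% list()))
  }
  out <- out_dir %||% cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  sc <- cfg$scenario
  seed <- as.integer(cfg$seed)
  files <- character(0)
  emit <- function(name, writer) {
    p <- file.path(out, name)
    writer(p)
    files <<- c(files, name)
    p
  }

  # --- simulate + profile each population ---------------------------------
  nonsyn <- rep_len(sc$nonsyn_fraction, sc$n_populations)
  summaries <- vector("list", sc$n_populations)
  snv_tabs <- list()
  saav_tabs <- list()
  profiled <- stage_log("simulate+profile", {
    for (i in seq_len(sc$n_populations)) {
      sim <- simulate_strain_community(
        n_contigs = 1L, contig_length = sc$contig_length,
        orf_density = sc$orf_density, proportions = sc$proportions,
        n_snvs = sc$n_snvs, nonsyn_fraction = nonsyn[i],
        depth = sc$depth, read_length = sc$read_length,
        error_rate = sc$error_rate, seed = seed + 13L * i
      )
      mag_id <- sprintf("POP_%02d", i)
      pu <- build_pileup(sim$alignments, sim$reference$contigs)
      snvs <- call_snvs(pu, th$min_coverage, th$min_departure)
      saavs <- call_saavs(sim$alignments, sim$reference$contigs,
                          sim$reference$orfs, th$min_coverage,
                          th$min_departure)
      summaries[[i]] <- summarize_mag(snvs, saavs, pu, mag_id,
                                      total_reads = sc$total_reads)
      if (nrow(snvs) > 0L) snv_tabs[[i]] <- cbind(mag_id = mag_id, snvs)
      if (nrow(saavs) > 0L) saav_tabs[[i]] <- cbind(mag_id = mag_id, saavs)
    }
    list(summary = do.call(rbind, summaries),
         snvs = do.call(rbind, snv_tabs),
         saavs = do.call(rbind, saav_tabs))
  })
  summary_tab <- profiled$summary
  summary_tab$group <- rep_len(sc$groups, sc$n_populations)
  emit("summary.tsv", function(p) write_summary_tsv(summary_tab, p))
  if (!is.null(profiled$snvs)) {
    emit("snvs.tsv", function(p) write_tsv(profiled$snvs, p))
  }
  if (!is.null(profiled$saavs)) {
    emit("saavs.tsv", function(p) write_tsv(profiled$saavs, p))
  }

  # --- group comparison of log SAAV/SNV ratios ----------------------------
  comparison <- stage_log("compare-ratios", {
    g <- unique(summary_tab$group)
    enough <- length(g) == 2L && all(table(summary_tab$group) >= 2L)
    if (!enough) {
      message("[compare-ratios] skipped: need two groups with >= 2 MAGs each")
      NULL
    } else {
      r1 <- summary_tab$saav_snv_ratio[summary_tab$group == g[1]]
      r2 <- summary_tab$saav_snv_ratio[summary_tab$group == g[2]]
      wt <- welch_t_test(r1, r2, log_transform = TRUE)
      df <- data.frame(group_1 = g[1], group_2 = g[2],
                       mean_log_ratio_1 = wt$mean_x, mean_log_ratio_2 = wt$mean_y,
                       t = wt$statistic, df = wt$df, p_value = wt$p_value)
      emit("group_comparison.tsv", function(p) write_tsv(df, p))
      df
    }
  })

  # --- ANI ladder over divergent pairs ------------------------------------
  ani_tab <- stage_log("ani", {
    base <- generate_reference(1L, max(3060L, sc$contig_length),
                               orf_density = 0, seed = seed + 101L)$contigs
    rows <- lapply(seq_along(sc$ani_divergences), function(j) {
      d <- sc$ani_divergences[j]
      pair <- generate_divergent_pair(base, d, seed = seed + 200L + j)
      r <- compute_ani(pair$genome_a, pair$genome_b,
                       min_identity = th$ani_min_identity,
                       min_fragment_coverage = th$ani_min_fragment_coverage)
      data.frame(divergence = d, ani = r$mean_of_directions,
                 fragments_accepted = r$forward$fragments_aligned,
                 fragments_total = r$forward$fragments_total)
    })
    tab <- do.call(rbind, rows)
    emit("ani.tsv", function(p) write_tsv(tab, p))
    tab
  })

  # --- pangenome: matrix, dendrogram, unique clusters, enrichment ---------
  pg <- stage_log("pangenome", {
    pgc <- sc$pangenome
    pan <- generate_pangenome(
      n_mags = pgc$n_mags, n_core = pgc$n_core, n_accessory = pgc$n_accessory,
      focal_pair_unique = pgc$focal_pair_unique,
      enriched_category = pgc$enriched_category,
      enrichment_strength = pgc$enrichment_strength,
      background_frequency = pgc$background_frequency, seed = seed + 301L
    )
    emit("presence_absence.tsv", function(p) {
      write_tsv(data.frame(cluster_id = rownames(pan$matrix), pan$matrix,
                           check.names = FALSE), p)
    })
    dend <- cluster_dendrogram(pan$matrix)
    emit("dendrogram.nwk", function(p) writeLines(dend$newick, p))
    uniq <- uniquely_shared(pan$matrix, pan$truth$focal_mags)
    emit("uniquely_shared.tsv", function(p) {
      write_tsv(data.frame(cluster_id = uniq), p)
    })
    enr <- cog_enrichment(
      focal_labels = unname(pan$cog_labels[uniq]),
      background_labels = unname(pan$cog_labels),
      repetitions = th$enrichment_repetitions,
      sample_size = th$enrichment_sample_size,
      levels = th$enrichment_levels, seed = seed + 302L
    )
    emit("enrichment.tsv", function(p) write_tsv(as.data.frame(enr), p))
    list(pangenome = pan, dendrogram = dend, uniquely_shared = uniq,
         enrichment = enr)
  })

  # --- manifest -----------------------------------------------------------
  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  files <- c(files, "config.yaml")
  manifest <- list(
    package = "magvar",
    version = as.character(utils::packageVersion("magvar")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(config = cfg, summary = summary_tab, comparison = comparison,
                 ani = ani_tab, pangenome = pg, manifest = manifest,
                 out_dir = out))
}
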