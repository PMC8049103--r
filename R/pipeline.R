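# End-to-end orchestration: strict YAML config validation, a master seed
# deterministically derived into per-stage seeds, digest-based stage
# skipping and a run manifest.

# Stable per-stage seed: polynomial byte hash of the stage name folded into
# the master seed, kept below 2^31 so it is a valid R integer seed.
stage_seed <- function(master, stage) {
  h <- as.double(master) %% 2147483647
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

pipeline_schema <- function() {
  list(
    seed = list(default = 1L, check = function(v) is.numeric(v) &&
                  length(v) == 1 && v == round(v),
                msg = "seed must be a single integer"),
    out_dir = list(default = NULL, check = function(v) is.character(v) &&
                     length(v) == 1,
                   msg = "out_dir must be a single path"),
    stages = list(default = c("simulate", "score", "trajectory", "kinetics",
                              "transcriptome", "repertoire"),
                  check = function(v) is.character(v) &&
                    all(v %in% c("simulate", "score", "trajectory",
                                 "kinetics", "transcriptome", "repertoire")),
                  msg = "stages must name known pipeline stages"),
    log_level = list(default = "info",
                     check = function(v) v %in% c("quiet", "info"),
                     msg = "log_level must be quiet or info"),
    simulate = list(nested = list(
      n_cells_per_arm_day = list(default = 1000L,
        check = function(v) is.numeric(v) && v >= 1,
        msg = "simulate.n_cells_per_arm_day must be >= 1"),
      bulk_n_genes = list(default = 2000L,
        check = function(v) is.numeric(v) && v >= 100,
        msg = "simulate.bulk_n_genes must be >= 100"),
      bulk_effect_size = list(default = 1,
        check = function(v) is.numeric(v) && v >= 0,
        msg = "simulate.bulk_effect_size must be >= 0"),
      bulk_dispersion = list(default = 40,
        check = function(v) is.numeric(v) && v > 0,
        msg = "simulate.bulk_dispersion must be > 0"),
      bulk_n_donors = list(default = 3L,
        check = function(v) is.numeric(v) && v >= 1,
        msg = "simulate.bulk_n_donors must be >= 1"),
      clono_n_clones = list(default = 1000L,
        check = function(v) is.numeric(v) && all(v >= 1),
        msg = "simulate.clono_n_clones must be >= 1"),
      clono_alpha = list(default = 1,
        check = function(v) is.numeric(v) && all(v >= 0),
        msg = "simulate.clono_alpha must be >= 0"),
      clono_depth = list(default = 50000L,
        check = function(v) is.numeric(v) && v >= 1,
        msg = "simulate.clono_depth must be >= 1"))),
    score = list(nested = list(
      cofactor = list(default = 5,
        check = function(v) is.numeric(v) && v > 0,
        msg = "score.cofactor must be > 0"),
      p_low = list(default = 1,
        check = function(v) is.numeric(v) && v >= 0 && v < 100,
        msg = "score.p_low must be in [0, 100)"),
      p_high = list(default = 99,
        check = function(v) is.numeric(v) && v > 0 && v <= 100,
        msg = "score.p_high must be in (0, 100]"),
      gate_threshold = list(default = 1.5,
        check = function(v) is.numeric(v),
        msg = "score.gate_threshold must be numeric"),
      n_subsample_per_arm = list(default = 2000L,
        check = function(v) is.null(v) || (is.numeric(v) && v >= 1),
        msg = "score.n_subsample_per_arm must be >= 1 or null"))),
    trajectory = list(nested = list(
      k_within = list(default = 15L,
        check = function(v) is.numeric(v) && v >= 1,
        msg = "trajectory.k_within must be >= 1"),
      k_between = list(default = 5L,
        check = function(v) is.numeric(v) && v >= 0,
        msg = "trajectory.k_between must be >= 0"),
      regions = list(default = 4L,
        check = function(v) is.numeric(v) && v >= 2,
        msg = "trajectory.regions must be >= 2"),
      terminal_day = list(default = NULL,
        check = function(v) is.null(v) || is.numeric(v),
        msg = "trajectory.terminal_day must be a day or null"),
      layout_iterations = list(default = 500L,
        check = function(v) is.numeric(v) && v >= 1,
        msg = "trajectory.layout_iterations must be >= 1"))),
    kinetics = list(nested = list(
      span = list(default = 0.75,
        check = function(v) is.numeric(v) && v > 0 && v <= 1,
        msg = "kinetics.span must be in (0, 1]"),
      degree = list(default = 1L,
        check = function(v) v %in% c(1, 2),
        msg = "kinetics.degree must be 1 or 2"),
      n_boot = list(default = 500L,
        check = function(v) is.numeric(v) && v >= 100,
        msg = "kinetics.n_boot must be >= 100"),
      n_perm = list(default = 999L,
        check = function(v) is.numeric(v) && v >= 999,
        msg = "kinetics.n_perm must be >= 999"))),
    transcriptome = list(nested = list(
      pseudocount = list(default = 1,
        check = function(v) is.numeric(v) && v >= 0,
        msg = "transcriptome.pseudocount must be >= 0"),
      n_top = list(default = 500L,
        check = function(v) is.numeric(v) && v >= 1,
        msg = "transcriptome.n_top must be >= 1"),
      pca_day = list(default = NULL,
        check = function(v) is.null(v) || is.numeric(v),
        msg = "transcriptome.pca_day must be a day or null"))),
    repertoire = list(nested = list(
      n_boot = list(default = 500L,
        check = function(v) is.numeric(v) && v >= 100,
        msg = "repertoire.n_boot must be >= 100"),
      margin = list(default = 0.25,
        check = function(v) is.numeric(v) && v > 0,
        msg = "repertoire.margin must be > 0")))
  )
}

#' Validate a pipeline configuration
#'
#' Reads YAML (or accepts a list), fills documented defaults, rejects
#' unknown keys by name and aggregates all range violations into a single
#' error report.
#'
#' @param config Path to a YAML file or a configuration list.
#' @return A validated, fully defaulted configuration list of class
#'   `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or a list")
  schema <- pipeline_schema()
  errors <- character()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    errors <- c(errors, paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")))
  out <- list()
  for (key in names(schema)) {
    spec <- schema[[key]]
    if (!is.null(spec$nested)) {
      sub <- if (is.null(config[[key]])) list() else config[[key]]
      if (!is.list(sub)) {
        errors <- c(errors, paste0(key, " must be a mapping"))
        sub <- list()
      }
      bad <- setdiff(names(sub), names(spec$nested))
      if (length(bad))
        errors <- c(errors, paste0("unknown config key(s): ",
                                   paste(paste0(key, ".", bad),
                                         collapse = ", ")))
      out[[key]] <- list()
      for (k2 in names(spec$nested)) {
        s2 <- spec$nested[[k2]]
        v <- if (k2 %in% names(sub)) sub[[k2]] else s2$default
        if (!(is.null(v) && is.null(s2$default)) && !isTRUE(s2$check(v)))
          errors <- c(errors, s2$msg)
        out[[key]][k2] <- list(v)
      }
    } else {
      v <- if (key %in% names(config)) config[[key]] else spec$default
      if (is.null(v) && key == "out_dir")
        errors <- c(errors, "out_dir is required")
      else if (!isTRUE(spec$check(v)))
        errors <- c(errors, spec$msg)
      out[key] <- list(v)
    }
  }
  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  structure(out, class = "run_config")
}

#' Default demonstration configuration
#'
#' A small but complete synthetic study: every stage enabled at sizes that
#' run in seconds.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return A validated `run_config`.
#' @export
demo_config <- function(out_dir, seed = 1) {
  validate_config(list(
    seed = seed, out_dir = out_dir,
    simulate = list(n_cells_per_arm_day = 400, bulk_n_genes = 600,
                    clono_n_clones = 300, clono_depth = 10000),
    score = list(n_subsample_per_arm = 800),
    kinetics = list(n_boot = 100),
    repertoire = list(n_boot = 200, margin = 0.25)))
}

md5_of <- function(paths) unname(tools::md5sum(paths))

md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  path
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Run the pipeline end-to-end
#'
#' Stages run in dependency order (simulate, then score, trajectory and
#' kinetics on the cytometry branch; transcriptome and repertoire on their
#' own branches). Per-stage seeds derive deterministically from the master
#' seed. A stage whose parameter-and-input digest matches the previous
#' manifest and whose outputs are intact is skipped. A stage failure aborts
#' with the stage named; prior outputs are preserved.
#'
#' @param config A `run_config` from [validate_config()] (or a path/list,
#'   validated on the fly).
#' @param force Rerun all stages even when digests match.
#' @return The run manifest (invisibly also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  info <- function(...) if (config$log_level != "quiet")
    message("[tcellrest] ", sprintf(...))
  prev <- NULL
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path))
    prev <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  manifest <- list(config_hash = md5_of_object(unclass(config)),
                   package_version =
                     as.character(utils::packageVersion("tcellrest")),
                   stages = list(), warnings = list())
  paths <- list(
    events = file.path(out_dir, "events.csv"),
    truth = file.path(out_dir, "cytometry_truth.tsv"),
    counts = file.path(out_dir, "bulk_counts.tsv"),
    bulk_samples = file.path(out_dir, "bulk_samples.tsv"),
    bulk_truth = file.path(out_dir, "bulk_truth.tsv"),
    clonotypes = file.path(out_dir, "clonotypes.tsv"),
    clono_samples = file.path(out_dir, "clonotype_samples.tsv"),
    scored = file.path(out_dir, "scored_events.csv"),
    edges = file.path(out_dir, "graph_edges.tsv"),
    layout = file.path(out_dir, "layout.csv"),
    regions = file.path(out_dir, "regions.tsv"),
    composition = file.path(out_dir, "region_composition.tsv"),
    summaries = file.path(out_dir, "region_score_summary.tsv"),
    kinetics = file.path(out_dir, "kinetics_fits.tsv"),
    trends = file.path(out_dir, "trend_tests.tsv"),
    signature = file.path(out_dir, "signature_kinetics.tsv"),
    pca = file.path(out_dir, "pca_scores.tsv"),
    loadings = file.path(out_dir, "pc1_top_loadings.tsv"),
    reprogramming = file.path(out_dir, "reprogramming_index.json"),
    diversity = file.path(out_dir, "diversity_report.tsv"),
    comparison = file.path(out_dir, "diversity_comparison.json"))

  stage_defs <- list(
    simulate = list(
      params = config$simulate, inputs = character(),
      outputs = c("events", "truth", "counts", "bulk_samples",
                  "bulk_truth", "clonotypes", "clono_samples"),
      run = function(seed) {
        p <- config$simulate
        sim <- simulate_cytometry(sim_config(
          n_cells_per_arm_day = p$n_cells_per_arm_day, seed = seed))
        write_events(sim$events, paths$events)
        write_tsv(sim$truth, paths$truth)
        bulk <- simulate_bulk_counts(
          design = default_bulk_design(p$bulk_n_donors),
          n_genes = p$bulk_n_genes, effect_size = p$bulk_effect_size,
          nb_dispersion = p$bulk_dispersion,
          seed = stage_seed(seed, "bulk"))
        write_tsv(cbind(gene = rownames(bulk$es$counts),
                        as.data.frame(bulk$es$counts)), paths$counts)
        write_tsv(bulk$es$samples, paths$bulk_samples)
        write_tsv(bulk$truth, paths$bulk_truth)
        clono <- simulate_clonotypes(
          n_clones = p$clono_n_clones, power_alpha = p$clono_alpha,
          depth = p$clono_depth, seed = stage_seed(seed, "clonotypes"))
        write_tsv(clono$tab$records, paths$clonotypes)
        write_tsv(clono$tab$samples, paths$clono_samples)
      }),
    score = list(
      params = config$score, inputs = "events", outputs = "scored",
      run = function(seed) {
        p <- config$score
        ev <- read_events(paths$events, "csv")
        ev <- arcsinh_transform(ev, p$cofactor)
        ev <- gate_events(ev, default_gate_rules(p$gate_threshold))
        if (!is.null(p$n_subsample_per_arm)) {
          arms <- unique(ev$data$arm)
          want <- min(p$n_subsample_per_arm * length(arms), nrow(ev$data))
          ev <- subsample(ev, want, stratify_by = c("arm", "day"),
                          seed = seed)
        }
        scored <- normalize_markers(ev, p$p_low, p$p_high)
        scored <- compute_scores(scored, default_panel_definition())
        write_scored_events(scored, paths$scored)
      }),
    trajectory = list(
      params = config$trajectory, inputs = "scored",
      outputs = c("edges", "layout", "regions", "composition", "summaries"),
      run = function(seed) {
        p <- config$trajectory
        scored <- read_scored_events(paths$scored)
        graph <- build_temporal_knn(scored, k_within = p$k_within,
                                    k_between = p$k_between)
        graph <- layout_graph(graph, iterations = p$layout_iterations,
                              seed = seed)
        edges <- data.frame(
          cell_a = graph$nodes$cell_id[graph$edges$from],
          cell_b = graph$nodes$cell_id[graph$edges$to],
          edge_type = graph$edges$type, stringsAsFactors = FALSE)
        write_tsv(edges, paths$edges)
        utils::write.csv(graph$layout, paths$layout, row.names = FALSE)
        assignment <- detect_regions(scored,
                                     terminal_day = p$terminal_day,
                                     R = p$regions, seed = seed)
        write_tsv(data.frame(cell_id = assignment$cell_id,
                             arm = assignment$arm,
                             region = assignment$region),
                  paths$regions)
        write_tsv(region_composition(assignment), paths$composition)
        write_tsv(region_score_summary(scored, assignment),
                  paths$summaries)
      }),
    kinetics = list(
      params = config$kinetics, inputs = "scored",
      outputs = c("kinetics", "trends"),
      run = function(seed) {
        p <- config$kinetics
        scored <- read_scored_events(paths$scored)
        kin <- score_kinetics(scored, span = p$span, degree = p$degree,
                              n_boot = p$n_boot, n_perm = p$n_perm,
                              seed = seed)
        fits <- do.call(rbind, lapply(names(kin$fits), function(key) {
          f <- kin$fits[[key]]
          parts <- strsplit(key, ".", fixed = TRUE)[[1]]
          data.frame(arm = parts[1], score_kind = parts[2],
                     day = f$grid, fitted = f$fitted, ci_low = f$ci_low,
                     ci_high = f$ci_high, stringsAsFactors = FALSE)
        }))
        write_tsv(fits, paths$kinetics)
        write_tsv(kin$trends, paths$trends)
      }),
    transcriptome = list(
      params = config$transcriptome,
      inputs = c("counts", "bulk_samples"),
      outputs = c("signature", "pca", "loadings", "reprogramming"),
      run = function(seed) {
        p <- config$transcriptome
        counts_df <- read_tsv(paths$counts)
        counts <- as.matrix(counts_df[, -1, drop = FALSE])
        rownames(counts) <- counts_df$gene
        samples <- read_tsv(paths$bulk_samples)
        es <- expr_set(counts, samples)
        norm <- normalize_counts(es, p$pseudocount)
        sig <- signature_kinetics(norm, samples, default_signatures())
        write_tsv(sig, paths$signature)
        n_top <- min(p$n_top, nrow(norm))
        pca <- pca_top_loadings(norm, samples, day = p$pca_day,
                                n_top = n_top)
        write_tsv(pca$scores, paths$pca)
        write_tsv(utils::head(pca$loadings, n_top), paths$loadings)
        idx <- reprogramming_index(pca$scores$PC1, pca$scores$arm)
        jsonlite::write_json(list(reprogramming_index = idx,
                                  day = pca$scores$day[1]),
                             paths$reprogramming, auto_unbox = TRUE,
                             digits = NA)
      }),
    repertoire = list(
      params = config$repertoire,
      inputs = c("clonotypes", "clono_samples"),
      outputs = c("diversity", "comparison"),
      run = function(seed) {
        p <- config$repertoire
        tab <- clonotype_table(read_tsv(paths$clonotypes),
                               read_tsv(paths$clono_samples))
        depths <- tapply(tab$records$count, tab$records$sample_id, sum)
        rarefy_to <- if (max(depths) / min(depths) > 2) min(depths)
                     else NULL
        if (is.null(rarefy_to))
          info("samples within 2-fold depth; rarefaction disabled")
        rep_df <- diversity(tab, rarefy_to = rarefy_to,
                            n_boot = p$n_boot, seed = seed)
        write_tsv(rep_df, paths$diversity)
        arms <- unique(tab$samples$arm)
        if (length(arms) >= 2) {
          cmp <- compare_diversity(tab, arms[1], arms[2],
                                   metric = "shannon", margin = p$margin,
                                   n_boot = p$n_boot,
                                   seed = stage_seed(seed, "compare"))
          jsonlite::write_json(unclass(cmp), paths$comparison,
                               auto_unbox = TRUE, digits = NA)
        }
      }))

  for (stage in config$stages) {
    def <- stage_defs[[stage]]
    in_files <- as.character(unlist(paths[def$inputs], use.names = FALSE))
    missing_in <- in_files[!file.exists(in_files)]
    if (length(missing_in))
      stop("stage '", stage, "' is missing input(s): ",
           paste(basename(missing_in), collapse = ", "),
           " (run earlier stages first)")
    signature <- md5_of_object(list(params = def$params,
                                    seed = config$seed,
                                    inputs = md5_of(in_files)))
    out_files <- unlist(paths[def$outputs], use.names = FALSE)
    prev_stage <- prev$stages[[stage]]
    if (!force && !is.null(prev_stage) &&
        identical(prev_stage$signature, signature) &&
        all(file.exists(out_files)) &&
        identical(unname(unlist(prev_stage$outputs)),
                  md5_of(out_files))) {
      info("stage '%s' up to date; skipped", stage)
      manifest$stages[[stage]] <- prev_stage
      manifest$stages[[stage]]$skipped <- TRUE
      next
    }
    info("running stage '%s'", stage)
    warns <- character()
    t0 <- proc.time()[["elapsed"]]
    result <- withCallingHandlers(
      tryCatch(def$run(stage_seed(config$seed, stage)),
               error = function(e)
                 stop("stage '", stage, "' failed: ",
                      conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    elapsed <- proc.time()[["elapsed"]] - t0
    manifest$stages[[stage]] <- list(
      skipped = FALSE, signature = signature, seconds = round(elapsed, 3),
      outputs = as.list(stats::setNames(md5_of(out_files),
                                        basename(out_files))))
    if (length(warns)) manifest$warnings[[stage]] <- warns
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}

#' Read scored events written by [write_scored_events()]
#'
#' Restores the `scored_events` object from the CSV and its JSON sidecar.
#'
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return A `scored_events`.
#' @export
read_scored_events <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  meta_cols <- c("cell_id", "sample", "arm", "day")
  score_cols <- intersect(c("exhaustion_score", "memory_score"), names(df))
  markers <- setdiff(names(df), c(meta_cols, score_cols))
  out <- structure(list(meta = df[meta_cols],
                        normalized = as.matrix(df[markers]),
                        bounds = side$bounds, p_low = side$p_low,
                        p_high = side$p_high,
                        quantile_type = side$quantile_type,
                        cofactor = side$cofactor,
                        exhaustion_score = NULL, memory_score = NULL,
                        panel = NULL),
                   class = "scored_events")
  if (length(score_cols) == 2) {
    out$exhaustion_score <- df$exhaustion_score
    out$memory_score <- df$memory_score
  }
  out
}
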