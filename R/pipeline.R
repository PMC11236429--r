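#' Assemble a pipeline configuration
#'
#' A plain list describing one full analysis: input (or synthetic) domains,
#' rarefaction depth, classification thresholds, grouping preset,
#' permutation counts, forward-selection alpha, and a base seed from which
#' every stage seed is derived.  The configuration round-trips losslessly
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param domains named list; each element either a synthetic spec
#'   (`list(model = "neutral", n_otus =, depth =, m =)` or
#'   `list(model = "niche", n_otus =, depth =, n_gradients =,
#'   niche_breadth =, ...)`) or file input
#'   (`list(otu_table = path, metadata = path, orientation =)`).
#' @param n_samples,n_landuse design of the simulated metadata (used when
#'   all domains are synthetic).
#' @param rarefy_depth target depth; `NULL` uses each domain's minimum
#'   sample total.
#' @param rare_cutoff,abundant_cutoff classification thresholds.
#' @param grouping `"paper"` or `"six"` (see [grouping_sets()]).
#' @param n_permutations permutations for Mantel/ANOSIM/selection/VPA.
#' @param alpha forward-selection entry threshold.
#' @param distance_mode PCNM geographic distance mode.
#' @param min_otus_ncm floor below which a subcommunity is reported as
#'   "not fitted" by the neutral model instead of erroring.
#' @param seed base integer seed; all stage seeds derive from it.
#' @param output_dir optional directory for stage outputs and the JSON
#'   report.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(domains,
                            n_samples = 46, n_landuse = 7,
                            rarefy_depth = NULL,
                            rare_cutoff = 1e-4, abundant_cutoff = 0.01,
                            grouping = c("paper", "six"),
                            n_permutations = 999, alpha = 0.05,
                            distance_mode = c("great_circle",
                                              "euclidean_on_degrees"),
                            min_otus_ncm = 50,
                            seed = 1, output_dir = NULL) {
  if (is.null(names(domains)) || any(names(domains) == ""))
    stop("'domains' must be a named list")
  structure(list(domains = domains, n_samples = n_samples,
                 n_landuse = n_landuse, rarefy_depth = rarefy_depth,
                 rare_cutoff = rare_cutoff,
                 abundant_cutoff = abundant_cutoff,
                 grouping = match.arg(grouping),
                 n_permutations = n_permutations, alpha = alpha,
                 distance_mode = match.arg(distance_mode),
                 min_otus_ncm = min_otus_ncm,
                 seed = as.integer(seed), output_dir = output_dir),
            class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# Deterministic per-domain/stage seed derivation (kept far below 2^31).
stage_seed <- function(base, domain_index, stage) {
  (base + 1009L * domain_index + 101L * stage) %% 2000000011L
}

#' Run the full subcommunity assembly pipeline
#'
#' Executes, for each configured domain: load or simulate -> rarefy ->
#' six-category classification -> per-subcommunity Bray-Curtis distance
#' decay against standardized environmental distance (Mantel), ANOSIM over
#' land use -> PCNM construction and forward selection of environmental
#' and spatial predictors -> variation partitioning -> neutral community
#' model fit.  All randomness derives from the config's base seed, so the
#' same configuration reproduces the same report; when `output_dir` is
#' set, stage tables (TSV) and the report (JSON) are written there.
#'
#' @param config a [pipeline_config()].
#' @return The report, an invisible list mirroring the domain x
#'   subcommunity grid.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  base <- config$seed

  # shared metadata: from the first file-backed domain, else simulated once
  meta <- NULL
  for (d in config$domains)
    if (!is.null(d$metadata)) { meta <- read_metadata(d$metadata); break }
  if (is.null(meta))
    meta <- simulate_metadata(config$n_samples, config$n_landuse, seed = base)

  env_dist <- environmental_distance(meta)
  pcnm <- pcnm_vectors(meta, distance_mode = config$distance_mode)
  env_block <- meta[, env_variables]
  spat_block <- as.data.frame(pcnm$vectors)

  report <- list(domains = list())
  for (i in seq_along(config$domains)) {
    dn <- names(config$domains)[i]
    spec <- config$domains[[i]]
    t0 <- Sys.time()

    if (!is.null(spec$otu_table)) {
      tab <- read_otu_table(spec$otu_table,
                            orientation = spec$orientation %||% "samples_as_rows")
      al <- align_samples(tab, meta)
      tab <- al$table
      dom_meta <- al$meta
    } else if (identical(spec$model, "neutral")) {
      tab <- simulate_neutral(n_samples = nrow(meta),
                              n_otus = spec$n_otus %||% 5000,
                              depth = spec$depth %||% 10000,
                              m = spec$m %||% 0.1,
                              seed = stage_seed(base, i, 1L))
      tab$counts <- `rownames<-`(tab$counts, meta$sample_id)
      dom_meta <- meta
    } else if (identical(spec$model, "niche")) {
      sim <- simulate_niche(n_otus = spec$n_otus %||% 2000,
                            depth = spec$depth %||% 10000,
                            n_gradients = spec$n_gradients %||% 2,
                            niche_breadth = spec$niche_breadth %||% 0.5,
                            noise_sd = spec$noise_sd %||% 0.3,
                            metadata = meta,
                            seed = stage_seed(base, i, 1L))
      tab <- sim$table
      dom_meta <- sim$meta
    } else stop("domain '", dn, "': neither input paths nor a known model")

    tab <- rarefy_table(tab, depth = config$rarefy_depth,
                        seed = stage_seed(base, i, 2L))
    part <- classify_taxa(tab, rare_cutoff = config$rare_cutoff,
                          abundant_cutoff = config$abundant_cutoff)
    summ <- partition_summary(part, tab)
    message(sprintf("[%s] %d samples x %d OTUs, depth %d; classified",
                    dn, nrow(tab$counts), ncol(tab$counts),
                    sum(tab$counts[1L, ])))

    groups <- grouping_sets(config$grouping)
    gres <- list()
    for (g in names(groups)) {
      in_group <- sum(part$category %in% groups[[g]])
      if (in_group < 5L) {
        gres[[g]] <- list(n_otus = in_group, skipped = TRUE,
                          reason = "fewer than 5 OTUs")
        next
      }
      sub <- subset_by_category(tab, part, groups[[g]])
      ok_samples <- rowSums(otu_counts(sub)) > 0
      sub2 <- subset_otu_table(sub, samples = which(ok_samples))
      ed <- if (all(ok_samples)) env_dist else
        environmental_distance(dom_meta[ok_samples, , drop = FALSE])
      bc <- bray_curtis(sub2)
      dd <- distance_decay_fit(bc, ed,
                               n_permutations = config$n_permutations,
                               seed = stage_seed(base, i, 3L))
      an <- anosim_test(bc, dom_meta$land_use[ok_samples],
                        n_permutations = config$n_permutations,
                        seed = stage_seed(base, i, 4L))
      Y <- hellinger(sub2)
      fs_env <- forward_select(Y, env_block[ok_samples, , drop = FALSE],
                               alpha = config$alpha,
                               n_permutations = config$n_permutations,
                               seed = stage_seed(base, i, 5L))
      fs_spat <- forward_select(Y, spat_block[ok_samples, , drop = FALSE],
                                alpha = config$alpha,
                                n_permutations = config$n_permutations,
                                seed = stage_seed(base, i, 6L))
      vp <- variation_partition(
        Y,
        if (length(fs_env$selected))
          env_block[ok_samples, fs_env$selected, drop = FALSE] else NULL,
        if (length(fs_spat$selected))
          spat_block[ok_samples, fs_spat$selected, drop = FALSE] else NULL,
        n_permutations = config$n_permutations,
        seed = stage_seed(base, i, 7L))
      ncm <- if (in_group >= config$min_otus_ncm) {
        fit <- fit_ncm(sub2, min_otus = config$min_otus_ncm,
                       require_even_depth = FALSE)
        env_counts <- envelope_partition(fit)
        list(fitted = TRUE, m = fit$m, Nm = fit$Nm, N = fit$N,
             r_squared = fit$r_squared, n_otus_used = fit$n_otus_used,
             envelope = as.list(env_counts))
      } else {
        list(fitted = FALSE, reason = sprintf(
          "only %d OTUs (floor %d)", in_group, config$min_otus_ncm))
      }
      gres[[g]] <- list(
        n_otus = in_group,
        mantel = list(r = dd$mantel$r, p = dd$mantel$p_value),
        anosim = list(R = an$R, p = an$p_value),
        distance_decay = list(slope = dd$slope, intercept = dd$intercept),
        selected_env = fs_env$selected,
        selected_pcnm = fs_spat$selected,
        vpa = c(as.list(vp$fractions),
                list(p_env = vp$p_env, p_spat = vp$p_spat)),
        ncm = ncm)
      if (!is.null(out_dir) && isTRUE(ncm$fitted)) {
        utils::write.table(fit$otu,
                           file.path(out_dir, sprintf("%s_%s_ncm.tsv", dn, g)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    report$domains[[dn]] <- list(
      n_samples = nrow(tab$counts), n_otus = ncol(tab$counts),
      depth = sum(tab$counts[1L, ]),
      partition_summary = summ, groups = gres)
    if (!is.null(out_dir))
      utils::write.table(summ,
                         file.path(out_dir, sprintf("%s_partition.tsv", dn)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("[%s] done in %.1f s", dn,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("subcomm")),
    base_seed = base,
    grouping = config$grouping,
    thresholds = c(rare = config$rare_cutoff,
                   abundant = config$abundant_cutoff),
    n_permutations = config$n_permutations)
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
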