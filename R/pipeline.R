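#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its conventional
#' default: the 20 km equal-area grid, the >=20-occurrence floor, 80/20
#' train/test splits repeated 10 times, TSS >= 0.5 model retention, the
#' 200 km hull and dispersal buffers, the >30% protection cutoff, 0.2/0.9
#' gap boundaries, 0.1/0.4 HMI class boundaries, CSH > 0.8 for great
#' expansion, 30%/50% priority fractions and +15%/+35% expansion fractions.
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param ... Named overrides of any default listed above.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # synthetic landscape
    nx = 30, ny = 30, cell_km = 20, n_species = 150, n_env_vars = 6,
    corr_len = 3, birth = 1, death = 0,
    niche_rate = 1, niche_breadth = 0.9, breadth_sdlog = 0.5,
    occupancy_threshold = 0.5,
    climate_shift = 0.5, shift_noise_sd = 0.1,
    pa_fraction = 0.15, pa_bias = 1,
    # niche models
    min_occ = 20, train_frac = 0.8, n_repeats = 10,
    pseudo_absence_ratio = 1, tss_min = 0.5, buffer_km = 200,
    dispersal = "full",
    # prioritization & assessment
    rule = "caz", pa_cutoff = 0.3,
    gap_low = 0.2, gap_high = 0.9,
    hmi_low = 0.1, hmi_high = 0.4,
    csh_expand = 0.8, aoa_quantile = 0.95,
    target_lower = 1000, target_upper = 250000, target_floor = 0.1,
    top_fractions = c(0.3, 0.5), add_fractions = c(0.15, 0.35),
    seed = 1
  )
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    abort("all config entries must be named")
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  if (cfg$pa_fraction < 0 || cfg$pa_fraction > 1) abort("pa_fraction in [0,1]")
  if (!cfg$dispersal %in% c("full", "limited", "none")) {
    abort("dispersal must be full, limited or none")
  }
  if (!cfg$rule %in% c("caz", "abf")) abort("rule must be caz or abf")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [pipeline_config()]
#'   arguments; unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Fit, evaluate, ensemble and binarize one species; returns NULL plus a log
# row when no replicate reaches the TSS floor.
fit_species_sdm <- function(occ_cells, climate, climate_future, grid, cfg,
                            seed) {
  seeds <- derive_seeds(seed, 2)
  pool <- setdiff(grid$cell_id, occ_cells)
  n_abs <- min(length(pool),
               max(5L, round(cfg$pseudo_absence_ratio * length(occ_cells))))
  if (n_abs < 2) {
    # near-ubiquitous species: no background to contrast against
    return(list(evals = tibble(sensitivity = numeric(), specificity = numeric(),
                               tss = numeric(), threshold = numeric(),
                               replicate = integer(), retained = logical()),
                range = NULL))
  }
  abs_cells <- with_seed(seeds[1], sample(pool, n_abs))
  splits <- split_train_test(occ_cells, abs_cells, cfg$train_frac,
                             cfg$n_repeats, seeds[2])

  evals <- vector("list", length(splits))
  scorers <- vector("list", length(splits))
  for (r in seq_along(splits)) {
    s <- splits[[r]]
    scorer <- suitability_scorer(s$train_pres, s$train_abs, climate)
    test_cells <- c(s$test_pres, s$test_abs)
    test_obs <- c(rep(TRUE, length(s$test_pres)), rep(FALSE, length(s$test_abs)))
    scores <- scorer(climate)$suitability[match(test_cells, climate$cell_id)]
    evals[[r]] <- tryCatch(
      maxtss_threshold(scores, test_obs)$evaluation |> mutate(replicate = r),
      error = function(e) tibble(sensitivity = NA_real_,
                                 specificity = NA_real_, tss = NA_real_,
                                 threshold = NA_real_, replicate = r)
    )
    scorers[[r]] <- scorer
  }
  evals <- bind_rows(evals)
  kept <- filter_models(evals, cfg$tss_min)
  if (attr(kept, "unmodellable")) {
    return(list(evals = evals |> mutate(retained = FALSE), range = NULL))
  }
  keep_idx <- kept$replicate

  cur_maps <- lapply(scorers[keep_idx], function(f) f(climate))
  fut_maps <- lapply(scorers[keep_idx], function(f) f(climate_future))
  cur_ens <- ensemble_median(cur_maps)
  fut_ens <- ensemble_median(fut_maps)

  fit_cells <- c(occ_cells, abs_cells)
  fit_obs <- c(rep(TRUE, length(occ_cells)), rep(FALSE, length(abs_cells)))
  thr <- maxtss_threshold(
    cur_ens$suitability[match(fit_cells, cur_ens$cell_id)], fit_obs)$threshold

  cur_bin <- cur_ens$cell_id[cur_ens$suitability >= thr]
  cur_bin <- clip_to_buffered_mcp(cur_bin, occ_cells, grid, cfg$buffer_km)
  fut_bin <- fut_ens$cell_id[fut_ens$suitability >= thr]
  fut_bin <- apply_dispersal(cur_bin, fut_bin, cfg$dispersal, grid,
                             cfg$buffer_km)
  list(
    evals = evals |> mutate(retained = .data$replicate %in% keep_idx),
    range = list(current = cur_bin, future = fut_bin, threshold = thr)
  )
}

#' Run the full analysis pipeline on a synthetic landscape
#'
#' Chains every stage end to end: synthetic landscape generation, per-species
#' suitability modelling (splits, TSS evaluation, TSS >= `tss_min`
#' retention, median ensembling, max-TSS binarization, hull clipping,
#' dispersal), branch feature construction, prioritization (current, future,
#' ABF cross-check, species-based benchmark, and a masked run with current
#' reserves locked in) and the protection assessment (gap analysis,
#' branch coverage, PD classes, HMI contrast, novel-climate flags,
#' expansion report). All randomness derives from `config$seed`; rerunning
#' with the same config reproduces the summary exactly.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, all tabular outputs, the
#'   tree, the summary JSON and a manifest are written there.
#' @return A list with `landscape`, `sdm` (evaluations + ranges),
#'   `branches`, `ranks`, `assessment`, `summary` (named scalars) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 4)

  ## stage 1: synthetic landscape -------------------------------------------
  land <- simulate_landscape(cfg)
  grid <- land$grid
  presences <- min_occurrence_filter(land$presences, cfg$min_occ)
  tree <- if (length(unique(presences$species)) < length(land$tree$tip.label)) {
    ape::keep.tip(land$tree, unique(presences$species))
  } else {
    land$tree
  }

  ## stage 2: niche models ---------------------------------------------------
  sp_list <- sort(unique(presences$species))
  sp_seeds <- derive_seeds(seeds[1], length(sp_list))
  occ_by_sp <- split(presences$cell_id, presences$species)
  sdm <- vector("list", length(sp_list))
  for (i in seq_along(sp_list)) {
    sdm[[i]] <- fit_species_sdm(occ_by_sp[[sp_list[i]]], land$climate,
                                land$climate_future, grid, cfg, sp_seeds[i])
  }
  names(sdm) <- sp_list
  unmod <- sp_list[vapply(sdm, function(x) is.null(x$range), TRUE)]
  if (length(unmod) > 0) {
    inform(sprintf("dropping %d unmodellable species (all TSS < %.2f)",
                   length(unmod), cfg$tss_min))
  }
  modelled <- setdiff(sp_list, unmod)
  evals <- bind_rows(lapply(sp_list, function(s) {
    sdm[[s]]$evals |> mutate(species = s, .before = 1)
  }))
  ranges_cur <- bind_rows(lapply(modelled, function(s) {
    tibble(species = s, cell_id = sdm[[s]]$range$current)
  }))
  ranges_fut <- bind_rows(lapply(modelled, function(s) {
    tibble(species = s, cell_id = sdm[[s]]$range$future)
  }))
  # a modelled range can end up below the floor after clipping; drop those
  ranges_cur <- min_occurrence_filter(ranges_cur, cfg$min_occ)
  keep_sp <- unique(ranges_cur$species)
  ranges_fut <- ranges_fut |> filter(.data$species %in% keep_sp)
  tree_mod <- ape::keep.tip(tree, keep_sp)

  ## stage 3: phylogenetic features -----------------------------------------
  branches_cur <- branch_occurrences(tree_mod, ranges_cur)
  fut_sp <- unique(ranges_fut$species)
  branches_fut <- branch_occurrences(ape::keep.tip(tree_mod, fut_sp),
                                     ranges_fut)
  pd <- faith_pd_per_cell(tree_mod, ranges_cur, cells = grid$cell_id)
  pd_cls <- pd_quantile_classes(pd$pd)

  ## stage 4: prioritization -------------------------------------------------
  prot_tbl <- protected_cells(land$pa_hmi, cfg$pa_cutoff)
  prot <- prot_tbl$cell_id[prot_tbl$protected]
  pseeds <- derive_seeds(seeds[2], 5)
  fs_cur <- build_branch_featureset(branches_cur, grid$cell_id, grid = grid)
  fs_fut <- build_branch_featureset(branches_fut, grid$cell_id, grid = grid)
  fs_mask <- build_branch_featureset(branches_cur, grid$cell_id, mask = prot,
                                     grid = grid)
  fs_sp <- build_species_featureset(ranges_cur, grid$cell_id, grid = grid)
  rank_cur <- run_prioritization(fs_cur, cfg$rule, pseeds[1])
  rank_fut <- run_prioritization(fs_fut, cfg$rule, pseeds[2])
  rank_alt <- run_prioritization(fs_cur, setdiff(c("caz", "abf"), cfg$rule),
                                 pseeds[3])
  rank_mask <- run_prioritization(fs_mask, cfg$rule, pseeds[4])
  rank_sp <- run_prioritization(fs_sp, cfg$rule, pseeds[5])

  ## stage 5: assessment -----------------------------------------------------
  f_main <- cfg$top_fractions[1]
  top_cur <- lapply(cfg$top_fractions, function(f) top_fraction(rank_cur, f))
  top_fut <- lapply(cfg$top_fractions, function(f) top_fraction(rank_fut, f))
  names(top_cur) <- names(top_fut) <- paste0("f", cfg$top_fractions)
  overlap <- scenario_overlap(top_cur[[1]], top_fut[[1]])

  gap_sp <- gap_analysis(ranges_cur, prot, cell_area = cfg$cell_km^2,
                         lower = cfg$target_lower, upper = cfg$target_upper,
                         floor = cfg$target_floor)
  gap_br <- gap_analysis(branches_cur |> select("branch_id", "cell_id"),
                         prot, cell_area = cfg$cell_km^2,
                         lower = cfg$target_lower, upper = cfg$target_upper,
                         floor = cfg$target_floor)
  csh_sp <- compute_csh(ranges_cur, ranges_fut, cfg$csh_expand)
  csh_br <- compute_csh(branches_cur |> select("branch_id", "cell_id"),
                        branches_fut |> select("branch_id", "cell_id"),
                        cfg$csh_expand)
  expansion <- expansion_report(rank_mask, prot, branches_cur,
                                pd_classes = pd_cls,
                                add_fractions = cfg$add_fractions)
  exp15 <- expansion$expansion |>
    filter(.data$add_fraction == cfg$add_fractions[1]) |> pull("cell_id")
  groups <- case_when(
    grid$cell_id %in% prot ~ "existing_pa",
    grid$cell_id %in% exp15 ~ "expansion",
    TRUE ~ "non_pa"
  )
  hmi_groups <- group_hmi_summary(land$pa_hmi$hmi, groups)
  aoa <- aoa_novel_climate(land$climate, land$climate_future,
                           cfg$aoa_quantile)
  sp_top <- top_fraction(rank_sp, f_main)
  br_top <- top_cur[[1]]

  summary <- list(
    n_species_input = cfg$n_species,
    n_species_modelled = length(keep_sp),
    n_unmodellable = length(unmod),
    mean_tss_retained = mean(evals$tss[evals$retained]),
    baseline_branch_coverage_pct = 100 * mean_branch_coverage(branches_cur, prot),
    coverage_after_expansion_pct = setNames(
      100 * expansion$summary$coverage_after,
      paste0("add_", expansion$summary$add_fraction)),
    priority_top_protected_pct =
      100 * mean(top_cur[[1]] %in% prot),
    pd_rank_caz_abf_r = compare_rank_maps(rank_cur, rank_alt),
    branch_coverage_pd_top_pct = 100 * mean_branch_coverage(branches_cur, br_top),
    branch_coverage_sr_top_pct = 100 * mean_branch_coverage(branches_cur, sp_top),
    gap_species_pct = 100 * mean(gap_sp$class == "gap"),
    gap_branch_pct = 100 * mean(gap_br$class == "gap"),
    covered_species_pct = 100 * mean(gap_sp$class == "covered"),
    lost_species_pct = 100 * mean(csh_sp$class == "lost"),
    greatly_expanded_species_pct = 100 * mean(csh_sp$class == "greatly_expanded"),
    aoa_novel_pct = 100 * mean(aoa$novel),
    overlap_cells = sum(overlap$status == "overlapped"),
    seed = cfg$seed
  )

  result <- list(
    landscape = land,
    presences = ranges_cur, presences_future = ranges_fut,
    tree = tree_mod,
    sdm = list(evaluations = evals, unmodellable = unmod),
    branches = list(current = branches_cur, future = branches_fut),
    pd = pd |> mutate(pd_class = pd_cls),
    ranks = list(current = rank_cur, future = rank_fut, alt_rule = rank_alt,
                 masked = rank_mask, species = rank_sp),
    assessment = list(protected = prot_tbl, gap_species = gap_sp,
                      gap_branches = gap_br, csh_species = csh_sp,
                      csh_branches = csh_br, expansion = expansion,
                      hmi_groups = hmi_groups, aoa = aoa,
                      overlap = overlap),
    summary = summary,
    config = cfg
  )
  if (!is.null(outdir)) {
    result$manifest <- write_pipeline_outputs(result, outdir)
  }
  result
}

# Write the canonical CSV/Newick/JSON outputs and return a manifest tibble.
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  readr::write_csv(result$landscape$grid, p("grid.csv"))
  readr::write_csv(result$landscape$climate, p("climate_current.csv"))
  readr::write_csv(result$landscape$climate_future, p("climate_future.csv"))
  readr::write_csv(result$landscape$pa_hmi, p("pa_hmi.csv"))
  readr::write_csv(result$presences, p("ranges_current.csv"))
  readr::write_csv(result$presences_future, p("ranges_future.csv"))
  readr::write_csv(result$sdm$evaluations, p("sdm_evaluations.csv"))
  readr::write_csv(result$branches$current, p("branch_features.csv"))
  readr::write_csv(result$pd, p("pd_per_cell.csv"))
  readr::write_csv(tidy(result$ranks$current), p("rank_current.csv"))
  readr::write_csv(tidy(result$ranks$masked), p("rank_masked.csv"))
  readr::write_csv(result$assessment$gap_species, p("gap_species.csv"))
  readr::write_csv(result$assessment$gap_branches, p("gap_branches.csv"))
  readr::write_csv(result$assessment$aoa, p("aoa_flags.csv"))
  ape::write.tree(result$tree, p("tree.nwk"))
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("grid.csv", "climate_current.csv", "climate_future.csv",
             "pa_hmi.csv", "ranges_current.csv", "ranges_future.csv",
             "sdm_evaluations.csv", "branch_features.csv", "pd_per_cell.csv",
             "rank_current.csv", "rank_masked.csv", "gap_species.csv",
             "gap_branches.csv", "aoa_flags.csv", "tree.nwk", "summary.json")
  manifest <- tibble(
    file = files,
    bytes = vapply(files, function(f) file.size(p(f)), 0.0),
    seed = result$config$seed,
    version = as.character(utils::packageVersion("phylozone"))
  )
  readr::write_csv(manifest, p("manifest.csv"))
  manifest
}
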