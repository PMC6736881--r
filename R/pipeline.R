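#' Run a pipeline stage with a reproducible configuration
#'
#' Drives the full analysis chain with a single configuration object (a
#' named list, or the path of a YAML file). Every stochastic step draws its
#' randomness from the single `seed` entry, and every run writes a
#' `manifest.json` echoing the configuration so results can be regenerated
#' exactly.
#'
#' Commands:
#' \describe{
#'   \item{simulate}{generate a synthetic dataset (see
#'     [simulate_dataset()]) and write it to `out`.}
#'   \item{align}{GPA + optional semilandmark sliding + symmetric component
#'     on landmark CSV files in `input_dir` (or on a just-simulated
#'     dataset); writes aligned coordinates.}
#'   \item{vlca}{fit the ancestral-shape model on population means over a
#'     preset or Newick tree; writes ancestral scores, confidence
#'     envelopes, landmark CSVs, a warped ancestor PLY and phylomorphospace
#'     CSVs.}
#'   \item{compare}{run between-group analyses A-D with passive specimens;
#'     writes distance tables and Procrustes-distance summaries.}
#'   \item{deviate}{surface deviation between two PLY/OBJ meshes; writes
#'     the report.}
#'   \item{signal}{multivariate phylogenetic signal (Kmult) of the
#'     population mean shapes on the tree.}
#' }
#'
#' @param command one of `"simulate"`, `"align"`, `"vlca"`, `"compare"`,
#'   `"deviate"`, `"signal"`.
#' @param config named list or YAML file path. Recognised entries: `seed`
#'   (mandatory), `out` (output directory), `tree` (preset name or Newick
#'   path), `rate`, `within_sd`, `individuals_per_taxon`,
#'   `sliding_iterations`, `symmetrize`, `analyses`, `n_perm`,
#'   `test_mesh`/`reference_mesh`, plus the generator arguments.
#' @return invisibly, a list of in-memory results per stage.
#' @export
run_pipeline <- function(command, config = list()) {
  command <- match.arg(command, c("simulate", "align", "vlca", "compare",
                                  "deviate", "signal"))
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must provide a seed")
  seed <- as.integer(config$seed)
  out <- config$out %||% file.path(tempdir(), paste0("paleoshape_", command))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- config; cfg$out <- out
  get_tree <- function() {
    tr <- cfg$tree %||% "h1"
    if (tr %in% c("h1", "h2", "h1b", "h2b")) build_hypothesis(tr) else read_newick(tr)
  }
  make_data <- function() {
    tmpl <- make_template(k_fixed = cfg$k_fixed %||% 56,
                          n_curves = cfg$n_curves %||% 4,
                          curve_len = cfg$curve_len %||% 29,
                          n_surface = cfg$n_surface %||% 608,
                          seed = seed)
    simulate_dataset(tree = get_tree(), template = tmpl,
                     rate = cfg$rate %||% 0.004,
                     within_sd = cfg$within_sd %||% 1,
                     individuals_per_taxon = cfg$individuals_per_taxon %||% 10,
                     seed = seed)
  }
  load_or_make <- function() {
    if (!is.null(cfg$input_dir)) {
      files <- sort(list.files(cfg$input_dir, pattern = "\\.csv$", full.names = TRUE))
      list(individuals = lapply(files, read_landmarks_csv),
           scheme = read_scheme(file.path(cfg$input_dir, "scheme.yaml")),
           tree = get_tree())
    } else make_data()
  }
  align_data <- function(ds) {
    g <- gpa(ds$individuals)
    it <- cfg$sliding_iterations %||% 3
    if (it > 0) g <- slide_semilandmarks(g, ds$scheme, iterations = it)
    if (isTRUE(cfg$symmetrize %||% TRUE)) g <- symmetric_component(g, ds$scheme)
    g
  }
  res <- switch(command,
    simulate = {
      ds <- make_data()
      write_dataset(ds, out)
      list(dataset = ds)
    },
    align = {
      ds <- load_or_make()
      g <- align_data(ds)
      for (cf in g$configs)
        write_landmarks_csv(cf, file.path(out, paste0(cf$specimen_id, "_aligned.csv")))
      utils::write.csv(data.frame(specimen = vapply(g$configs, `[[`, "", "specimen_id"),
                                  centroid_size = g$centroid_sizes),
                       file.path(out, "centroid_sizes.csv"), row.names = FALSE)
      list(dataset = ds, aligned = g)
    },
    vlca = {
      ds <- load_or_make()
      g <- align_data(ds)
      means <- population_mean_shapes(g)
      fit <- vlca(means, ds$tree)
      sc <- coef(fit)
      utils::write.csv(sc, file.path(out, "ancestral_scores.csv"))
      ci <- confint(fit)
      utils::write.csv(ci$lower, file.path(out, "ancestral_ci_lower.csv"))
      utils::write.csv(ci$upper, file.path(out, "ancestral_ci_upper.csv"))
      root_lm <- fit$node_landmarks[[1]]
      write_landmarks_csv(landmark_config(root_lm, "vLCA_root"),
                          file.path(out, "vlca_root_landmarks.csv"))
      if (!is.null(ds$base_shape)) {
        # template base shape lies on the reference ellipsoid surface;
        # rescale the unit-size ancestor back to template scale for warping
        s_mm <- csize(center_config(ds$base_shape))
        warped <- warp_reference(ellipsoid_mesh(), ds$base_shape, root_lm * s_mm)
        write_ply(warped, file.path(out, "vlca_root.ply"))
      }
      pm <- phylomorphospace(fit, pcs = seq_len(min(3, ncol(sc))))
      utils::write.csv(pm$points, file.path(out, "phylomorphospace_points.csv"),
                       row.names = FALSE)
      utils::write.csv(pm$edges, file.path(out, "phylomorphospace_edges.csv"),
                       row.names = FALSE)
      utils::write.csv(pm$ellipses, file.path(out, "phylomorphospace_ellipses.csv"),
                       row.names = FALSE)
      list(fit = fit, phylomorphospace = pm)
    },
    compare = {
      ds <- load_or_make()
      g <- align_data(ds)
      means <- population_mean_shapes(g)
      fit <- vlca(means, ds$tree)
      root_id <- rownames(coef(fit))[1]
      passive_full <- list(vLCA = fit$node_landmarks[[root_id]])
      results <- list()
      for (an in (cfg$analyses %||% c("A", "B", "C", "D"))) {
        spec <- make_analysis_spec(an, ds$scheme)
        keep_cfg <- Filter(function(cf)
          !(cf$specimen_id %in% spec$excluded_specimens), ds$individuals)
        sub <- lapply(keep_cfg, function(cf)
          landmark_config(cf$coords[spec$landmark_indices, , drop = FALSE],
                          cf$specimen_id, group = cf$group))
        pas <- lapply(passive_full, function(m)
          m[spec$landmark_indices, , drop = FALSE])
        ga <- gpa(c(sub, lapply(names(pas), function(nm)
          landmark_config(pas[[nm]], nm))))
        np <- length(pas)
        ind <- ga$configs[seq_len(length(sub))]
        pv <- ga$configs[length(sub) + seq_len(np)]
        names(pv) <- names(pas)
        bg <- bgpca(ind, passive = pv)
        dt <- euclidean_distance_table(bg)
        write_distance_table(dt, file.path(out, paste0("distances_", an, ".csv")))
        pr <- procrustes_distance_report(
          structure(list(configs = ind, consensus = ga$consensus,
                         centroid_sizes = rep(1, length(ind)),
                         n_iterations = ga$n_iterations),
                    class = "aligned_sample"), pv)
        utils::write.csv(pr$summary,
                         file.path(out, paste0("procdist_", an, ".csv")),
                         row.names = FALSE)
        results[[an]] <- list(spec = spec, bgpca = bg, distances = dt,
                              procdist = pr)
      }
      results
    },
    deviate = {
      read_mesh <- function(p)
        if (grepl("\\.obj$", p, ignore.case = TRUE)) read_obj(p) else read_ply(p)
      if (is.null(cfg$test_mesh) || is.null(cfg$reference_mesh))
        stop("deviate needs test_mesh and reference_mesh paths")
      rep_ <- deviation(read_mesh(cfg$test_mesh), read_mesh(cfg$reference_mesh),
                        mode = cfg$mode %||% "nearest_point")
      write_deviation_report(rep_, file.path(out, "deviation"))
      list(report = rep_)
    },
    signal = {
      ds <- load_or_make()
      g <- align_data(ds)
      means <- population_mean_shapes(g)
      Y <- do.call(rbind, lapply(means, vec_shape))
      rownames(Y) <- names(means)
      ks <- kmult(ds$tree, Y, n_perm = cfg$n_perm %||% 999, seed = seed)
      jsonlite::write_json(list(K = ks$K, p_value = ks$p_value,
                                n_perm = ks$n_perm, seed = ks$seed),
                           file.path(out, "kmult.json"),
                           auto_unbox = TRUE, digits = NA)
      list(kmult = ks)
    })
  manifest <- list(command = command, config = cfg, seed = seed,
                   package_version = as.character(utils::packageVersion("paleoshape")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
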