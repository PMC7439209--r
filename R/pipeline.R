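#' Configure an end-to-end pipeline run
#'
#' Bundles every stage configuration plus the output directory and one
#' global seed from which all stage seeds are derived deterministically.
#'
#' @param out_dir output directory (created if absent).
#' @param generator a [generator_config()].
#' @param density a [density_config()].
#' @param sparsity a [sparsity_grid()].
#' @param randomization a [randomization_config()] for normalized global
#'   metrics.
#' @param target_per_hemisphere network nodes per hemisphere (default 256).
#' @param alpha,q significance and FDR levels for the statistics stage.
#' @param write_weights write per-subject weight matrices as TSV artifacts.
#' @param write_binaries also write every binarized matrix (large).
#' @param write_vertex_tables write per-subject vertex TSVs.
#' @param seed global pipeline seed; overrides the generator and
#'   randomization seeds.
#' @return a `hemimorph_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            generator = generator_config(),
                            density = density_config(),
                            sparsity = sparsity_grid(),
                            randomization = randomization_config(),
                            target_per_hemisphere = 256L,
                            alpha = 0.05, q = 0.05,
                            write_weights = TRUE,
                            write_binaries = FALSE,
                            write_vertex_tables = FALSE,
                            seed = 1L) {
  if (!is_count(seed, 0)) stop_config("`seed` must be a non-negative integer")
  generator$seed <- derive_seed(seed, 10L)
  randomization$seed <- derive_seed(seed, 11L)
  structure(
    list(out_dir = out_dir, generator = generator, density = density,
         sparsity = sparsity, randomization = randomization,
         target_per_hemisphere = as.integer(target_per_hemisphere),
         alpha = alpha, q = q,
         write_weights = isTRUE(write_weights),
         write_binaries = isTRUE(write_binaries),
         write_vertex_tables = isTRUE(write_vertex_tables),
         seed = as.integer(seed)),
    class = "hemimorph_pipeline_config"
  )
}

#' Build a pipeline configuration from a YAML file
#'
#' The YAML mirrors the constructor arguments: top-level keys `out_dir`,
#' `seed`, `target_per_hemisphere`, `alpha`, `q`, `write_weights`,
#' `write_binaries`, `write_vertex_tables`, plus nested mappings
#' `generator`, `density`, `randomization` and a `sparsity` mapping with
#' `from`/`to`/`by`. Generator effects are a list of mappings with keys
#' `region`, `hemisphere`, `gender`, `mean_shift`, `sd_scale`.
#'
#' @param path YAML file path.
#' @param out_dir override for the configured output directory.
#' @return a `hemimorph_pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator %||% list()
  if (!is.null(gen_args$effect_specs)) {
    gen_args$effect_specs <- lapply(gen_args$effect_specs, function(e) {
      do.call(effect_spec, e)
    })
  }
  args <- list(
    out_dir = out_dir %||% y$out_dir %||% stop_config("`out_dir` required"),
    generator = do.call(generator_config, gen_args),
    density = do.call(density_config, y$density %||% list()),
    randomization = do.call(randomization_config, y$randomization %||% list()),
    sparsity = do.call(sparsity_grid, y$sparsity %||% list())
  )
  for (k in c("target_per_hemisphere", "alpha", "q", "write_weights",
              "write_binaries", "write_vertex_tables", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

config_as_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), strip)
    } else {
      x
    }
  }
  strip(config)
}

#' Run the full analysis pipeline
#'
#' Stage order: generate the synthetic cohort, apply the cohort filter,
#' upsample the parcellation, then per subject build both hemispheric
#' networks and their sparsity-stacked metrics, integrate over sparsity,
#' derive asymmetry indexes, and run the group statistics. Each stage
#' writes its artifacts under `config$out_dir` and records the md5 sums of
#' its inputs in `run_state.json`; re-running with unchanged inputs skips
#' completed stages, and re-running in a fresh directory reproduces
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) list with `manifest`, `parcellation`, `metrics`
#'   (global/local tibbles), `integrated`, `ai`, `anova`, `ttests`, and
#'   `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "hemimorph_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  path <- function(...) file.path(config$out_dir, ...)

  config_path <- path("config.yaml")
  writeLines(yaml::as.yaml(config_as_list(config)), config_path)
  state <- read_run_state(path("run_state.json"))

  stage <- function(name, inputs, outputs, run) {
    in_md5 <- unname(tools::md5sum(inputs))
    cached <- !is.null(state[[name]]) &&
      identical(unlist(state[[name]]$inputs), in_md5) &&
      all(file.exists(outputs))
    if (cached) {
      say("[%s] up to date, skipping", name)
    } else {
      say("[%s] running", name)
      run()
      state[[name]] <<- list(inputs = in_md5, outputs = outputs)
      write_run_state(state, path("run_state.json"))
    }
    outputs
  }

  manifest_path <- path("manifest.csv")
  filtered_path <- path("manifest_filtered.csv")
  template_path <- path("surface_template.tsv")
  template <- NULL

  stage("generate", config_path,
        c(manifest_path, template_path), function() {
    template <<- generate_surface(config$generator)
    tpl <- template
    tpl$thickness <- 1  # placeholder so the template passes table validation
    write_vertex_table(tpl, template_path)
    write_cohort_manifest(cohort_manifest(config$generator), manifest_path)
  })
  if (is.null(template)) {
    template <- read_vertex_table(template_path)
    template$thickness <- NULL
  }
  manifest <- read_cohort_manifest(manifest_path)

  stage("filter", c(config_path, manifest_path), filtered_path, function() {
    write_cohort_manifest(
      filter_cohort(manifest, config$generator$handedness_min), filtered_path)
  })
  manifest <- read_cohort_manifest(filtered_path)

  parc_vertex_path <- path("parcellation_vertices.tsv")
  parc_sub_path <- path("parcellation_subregions.tsv")
  stage("parcellate", c(config_path, template_path),
        c(parc_vertex_path, parc_sub_path), function() {
    parc <- upsample_parcellation(template, config$target_per_hemisphere,
                                  seed = derive_seed(config$seed, 12L))
    write_parcellation(parc, parc_vertex_path, parc_sub_path)
  })
  parcellation <- read_parcellation(parc_vertex_path, parc_sub_path)

  global_path <- path("metrics_global.csv")
  local_path <- path("metrics_local.csv")
  integrated_path <- path("integrated.csv")
  ai_path <- path("ai.csv")
  stage("networks", c(config_path, filtered_path, template_path,
                      parc_vertex_path, parc_sub_path),
        c(global_path, local_path, integrated_path, ai_path), function() {
    basis <- cohort_field_basis(template, config$generator)
    full_manifest <- read_cohort_manifest(manifest_path)
    acc_g <- list(); acc_l <- list(); acc_i <- list(); acc_a <- list()
    for (sid in manifest$subject_id) {
      i <- match(sid, full_manifest$subject_id)
      subject <- generate_subject(template, config$generator,
                                  full_manifest$gender[i], i, basis = basis)
      if (config$write_vertex_tables) {
        dir.create(path("subjects"), showWarnings = FALSE)
        write_vertex_table(subject, path("subjects", paste0(sid, ".tsv")))
      }
      nets <- build_hemispheric_networks(subject, parcellation,
                                         config$density, config$sparsity,
                                         subject_id = sid)
      if (config$write_weights || config$write_binaries) {
        dir.create(path("networks"), showWarnings = FALSE)
        for (h in c("L", "R")) {
          if (config$write_weights) {
            write_matrix_artifact(
              matrix_artifact(nets[[h]]$weights, sid, h, "weights",
                              node_labels = nets[[h]]$node_ids),
              path("networks", sprintf("%s_%s_weights.tsv", sid, h)))
          }
          if (config$write_binaries) {
            for (k in names(nets[[h]]$binaries)) {
              write_matrix_artifact(
                matrix_artifact(nets[[h]]$binaries[[k]], sid, h, "binary",
                                sparsity = as.numeric(k),
                                node_labels = nets[[h]]$node_ids),
                path("networks", sprintf("%s_%s_binary_%s.tsv", sid, h, k)))
            }
          }
        }
      }
      rcfg <- randomization_config(
        n_random = config$randomization$n_random,
        swaps_per_edge = config$randomization$swaps_per_edge,
        seed = derive_seed(config$randomization$seed, 13L, i)
      )
      met <- lapply(nets, network_metrics, randomization = rcfg)
      integ <- integrate_subject_metrics(met, parcellation, config$sparsity)
      ai <- subject_asymmetry(integ)
      for (h in c("L", "R")) {
        gg <- met[[h]]$global
        gg$subject_id <- sid; gg$hemisphere <- h
        ll <- met[[h]]$local
        ll$subject_id <- sid; ll$hemisphere <- h
        acc_g[[paste(sid, h)]] <- gg
        acc_l[[paste(sid, h)]] <- ll
      }
      ig <- dplyr::bind_rows(
        dplyr::mutate(integ$global, scope = "global", region = NA_character_),
        dplyr::mutate(integ$local, scope = "region")
      )
      ig$subject_id <- sid
      acc_i[[sid]] <- ig
      ai$subject_id <- sid
      acc_a[[sid]] <- ai
      say("  subject %s done", sid)
    }
    readr::write_csv(dplyr::bind_rows(acc_g), global_path)
    readr::write_csv(dplyr::bind_rows(acc_l), local_path)
    readr::write_csv(dplyr::bind_rows(acc_i), integrated_path)
    readr::write_csv(dplyr::bind_rows(acc_a), ai_path)
  })
  metrics_global <- readr::read_csv(global_path, show_col_types = FALSE)
  metrics_local <- readr::read_csv(local_path, show_col_types = FALSE)
  integrated <- readr::read_csv(integrated_path, show_col_types = FALSE)
  ai <- readr::read_csv(ai_path, show_col_types = FALSE)

  anova_global_path <- path("stats_anova_global.csv")
  anova_local_path <- path("stats_anova_local.csv")
  ttest_global_path <- path("stats_ttest_global.csv")
  ttest_local_path <- path("stats_ttest_local.csv")
  stats_paths <- c(anova_global_path, anova_local_path,
                   ttest_global_path, ttest_local_path)
  stage("stats", c(config_path, integrated_path, ai_path, filtered_path),
        stats_paths, function() {
    av <- anova_battery(integrated, manifest, q = config$q)
    tt <- ai_test_battery(ai, manifest, alpha = config$alpha, q = config$q)
    readr::write_csv(av$global, anova_global_path)
    readr::write_csv(av$local %||% tibble(), anova_local_path)
    readr::write_csv(tt$global, ttest_global_path)
    readr::write_csv(tt$local %||% tibble(), ttest_local_path)
  })

  run_manifest <- list(
    package_version = as.character(utils::packageVersion("hemimorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(config_path)),
    finished = TRUE
  )
  jsonlite::write_json(run_manifest, path("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    manifest = manifest,
    parcellation = parcellation,
    metrics = list(global = metrics_global, local = metrics_local),
    integrated = integrated,
    ai = ai,
    anova = list(global = readr::read_csv(anova_global_path,
                                          show_col_types = FALSE),
                 local = readr::read_csv(anova_local_path,
                                         show_col_types = FALSE)),
    ttests = list(global = readr::read_csv(ttest_global_path,
                                           show_col_types = FALSE),
                  local = readr::read_csv(ttest_local_path,
                                          show_col_types = FALSE)),
    paths = list(out_dir = config$out_dir)
  ))
}

read_run_state <- function(path) {
  if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    list()
  }
}

write_run_state <- function(state, path) {
  jsonlite::write_json(state, path, auto_unbox = TRUE, pretty = TRUE)
}
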