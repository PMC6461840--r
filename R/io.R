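#' Read and write pipeline tables
#'
#' Count matrices are TSV with genes in rows (first column `gene_id`) and
#' samples in columns; sample metadata, marker and annotation tables are
#' TSV; chemistry tables are CSV; spectra are CSV with the axis in the
#' first column and one column per sample.  Every writer round-trips
#' through its reader to an equal in-memory object.
#'
#' @param counts Genes x samples matrix.
#' @param path File path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname pipeline_io
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname pipeline_io
#' @param metadata Sample metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname pipeline_io
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, colClasses = c(time_point = "character"))
}

#' @rdname pipeline_io
#' @param chem Chemistry data.frame.
#' @export
write_chemistry <- function(chem, path) {
  utils::write.csv(chem, path, row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline_io
#' @export
read_chemistry <- function(path) {
  utils::read.csv(path)
}

#' @rdname pipeline_io
#' @param spectra A `spectra_matrix` object.
#' @export
write_spectra <- function(spectra, path) {
  df <- data.frame(axis = spectra$axis, t(spectra$intensities),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline_io
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ints <- t(as.matrix(df[, -1, drop = FALSE]))
  structure(list(axis = df[[1]], intensities = ints,
                 sample_ids = rownames(ints)),
            class = "spectra_matrix")
}

#' Write a nested result object as JSON
#'
#' @param x List to serialise.
#' @param path Output path.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

# polynomial rolling hash over the deparsed config; stable fingerprint for
# the manifest (kept in double precision, reduced mod 2^31)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[order(names(config))]), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' All thresholds and defaults used by [run_all()], validated on load:
#' unknown keys are rejected.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(seed = 1L,
       glucose_threshold = 1,
       ammonium_detect_frac = 0.02,
       pcd_lag = 150,
       ev_threshold = 99.9,
       k_max = 6,
       mcr_restarts = 5,
       fold_threshold = 2,
       alpha = 0.01,
       top_quantile = 0.2,
       min_fold = 2,
       B = 199,
       toc_mode = "divide",
       n_per_pattern = 20,
       n_null = 100,
       lfc = 2,
       dispersion = 0.02,
       noise_cv = 0.05)
}

#' @rdname default_config
#' @param config Candidate configuration list.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(ref, config)
  stopifnot(out$glucose_threshold > 0, out$B >= 19,
            out$alpha > 0, out$alpha < 1,
            out$fold_threshold >= 1, out$ev_threshold > 0)
  out
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full simulated pipeline
#'
#' Executes simulate -> phases -> spectroscopy (MCR, Fe pre-edge, N
#' speciation) -> Ox/C3-G -> differential expression -> response types ->
#' permutation test, writing all outputs plus a manifest JSON (seeds,
#' configuration, configuration hash, stage outputs) to `out_dir`.
#'
#' @param config Configuration list (see [default_config()]); partial
#'   lists are completed with defaults.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_all <- function(config = list(), out_dir = tempfile("ecmsom_run_")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  manifest <- list(package = "ecmsom",
                   version = as.character(utils::packageVersion("ecmsom")),
                   seed = cfg$seed, config = cfg, config_hash = config_hash(cfg),
                   outputs = list())

  # 1. chemistry + phases (two species archetypes)
  chem <- run_stage("chemistry", {
    d1 <- sim_design("P_involutus_like", seed = cfg$seed)
    d2 <- sim_design("L_bicolor_like", seed = cfg$seed + 1L)
    p1 <- chem_params(post_depletion = "decline", noise_cv = cfg$noise_cv,
                      ammonium_detect_frac = cfg$ammonium_detect_frac,
                      glucose_threshold = cfg$glucose_threshold)
    p2 <- chem_params(post_depletion = "plateau", noise_cv = cfg$noise_cv,
                      ammonium_detect_frac = cfg$ammonium_detect_frac,
                      glucose_threshold = cfg$glucose_threshold)
    rbind(simulate_chemistry(d1, p1), simulate_chemistry(d2, p2))
  })
  write_chemistry(chem, path("chemistry.csv"))
  phases <- run_stage("phases", {
    lapply(split(chem, chem$species), detect_phases,
           glucose_threshold = cfg$glucose_threshold, pcd_lag = cfg$pcd_lag)
  })
  write_result_json(lapply(phases, function(p) {
    list(times = as.list(p$times), labels = p$labels)
  }), path("phases.json"))
  manifest$outputs$phases <- "phases.json"

  # 2. FTIR time series + MCR-ALS
  mcr <- run_stage("mcr", {
    truth <- spectral_ground_truth()
    spectra <- simulate_spectra(truth, seed = cfg$seed)
    write_spectra(spectra, path("ftir.csv"))
    k <- select_components(spectra, k_max = cfg$k_max,
                           ev_threshold = cfg$ev_threshold,
                           n_restarts = cfg$mcr_restarts, seed = cfg$seed)
    fit <- fit_mcr(spectra, k = as.integer(k),
                   n_restarts = cfg$mcr_restarts, seed = cfg$seed)
    utils::write.csv(data.frame(sample = rownames(fit$C), fit$C),
                     path("mcr_concentrations.csv"), row.names = FALSE)
    utils::write.csv(data.frame(axis = fit$axis, fit$S),
                     path("mcr_spectra.csv"), row.names = FALSE)
    fit
  })
  write_result_json(list(k = mcr$k, explained_variance = mcr$explained_variance,
                         n_iter = mcr$n_iter, converged = mcr$converged),
                    path("mcr.json"))
  manifest$outputs$mcr <- "mcr.json"

  # 3. Fe pre-edge series: reduction during AG/ND, reoxidation at CD/pCD in
  # the Fenton-chemistry archetype; no change in the other species
  fe <- run_stage("fe_preedge", {
    frac <- list(P_involutus_like = c(t1 = 0.7, t2 = 0.8, t3 = 0.2, t4 = 0.1),
                 L_bicolor_like = c(t1 = 0.15, t2 = 0.15, t3 = 0.1, t4 = 0.1))
    res <- list()
    i <- 0L
    for (sp in names(frac)) {
      for (tp in names(frac[[sp]])) {
        for (rep in 1:2) {
          i <- i + 1L
          spec <- simulate_preedge(frac[[sp]][[tp]], noise_sd = 2e-3,
                                   seed = cfg$seed + i)
          fit <- fit_preedge(spec)
          res[[i]] <- data.frame(species = sp, time_point = tp, replicate = rep,
                                 centroid = fit$centroid,
                                 ferrous_fraction = fit$ferrous_fraction)
        }
      }
    }
    res <- do.call(rbind, res)
    res
  })
  fe_anova <- run_stage("fe_anova", {
    lapply(split(fe, fe$species), function(d) {
      compare_centroids(split(d$centroid, d$time_point))
    })
  })
  write_result_json(list(centroids = fe,
                         anova = lapply(fe_anova, function(a) {
                           list(F = a$F, p = a$p)
                         })),
                    path("fe_preedge.json"))
  manifest$outputs$fe_preedge <- "fe_preedge.json"

  # 4. N speciation + ordination: amide-rich early, heterocyclic-enriched
  # after carbon depletion
  nspec <- run_stage("n_speciation", {
    set.seed(cfg$seed + 100L)
    early <- c(pyridine = 0.8, nitrile = 0.6, amide = 2.4, pyrrole = 0.9)
    late <- c(pyridine = 1.3, nitrile = 0.6, amide = 1.4, pyrrole = 1.5)
    areas <- rbind(
      t(replicate(4, early * (1 + stats::rnorm(4, 0, 0.05)))),
      t(replicate(4, late * (1 + stats::rnorm(4, 0, 0.05)))))
    rel <- n_speciation(pmax(areas, 0))
    list(table = rel, pca = pca_ordination(rel),
         group = rep(c("t1_t2", "t3_t4"), each = 4))
  })
  write_result_json(list(abundances = nspec$table,
                         variance_explained = nspec$pca$variance_explained),
                    path("n_speciation.json"))
  manifest$outputs$n_speciation <- "n_speciation.json"

  # 5. lignin oxidation marker
  oxc3g <- run_stage("ox_c3g", {
    set.seed(cfg$seed + 200L)
    markers <- data.frame(
      sample_id = c("SOMt0", paste0("t", 1:4)),
      ox_g = c(1.0, 1.05, 1.9, 2.6, 2.7),
      c3g = c(1.0, 1.00, 0.95, 0.90, 0.85),
      toc = c(100, 98, 90, 80, 75),
      control = c(TRUE, FALSE, FALSE, FALSE, FALSE))
    ratios <- ox_c3g(markers, toc_mode = cfg$toc_mode)
    utils::write.table(ratios, path("oxc3g.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ratios
  })
  manifest$outputs$ox_c3g <- "oxc3g.tsv"

  # 6. counts -> DE -> response types -> permutation test
  types <- run_stage("response_types", {
    design <- sim_design(seed = cfg$seed)
    templates <- gene_templates(n_per_pattern = cfg$n_per_pattern,
                                n_null = cfg$n_null, lfc = cfg$lfc,
                                dispersion = cfg$dispersion, seed = cfg$seed)
    sim <- simulate_counts(design, templates, seed = cfg$seed)
    write_counts(sim$counts, path("counts.tsv"))
    write_metadata(sim$metadata, path("metadata.tsv"))
    write_metadata(templates[c("gene_id", "category_path")],
                   path("annotations.tsv"))
    tc <- test_time_course(sim$counts, sim$metadata, alpha = cfg$alpha)
    rp <- response_profiles(sim$counts, sim$metadata,
                            fold_threshold = cfg$fold_threshold,
                            alpha = cfg$alpha)
    ct <- count_types(rp$profiles)
    hier <- build_hierarchy(templates[c("gene_id", "category_path")])
    perm <- permutation_test(sim$counts, sim$metadata, hier, B = cfg$B,
                             seed = cfg$seed,
                             fold_threshold = cfg$fold_threshold,
                             alpha = cfg$alpha)
    utils::write.table(rp$profiles, path("response_profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(time_course = tc, profiles = rp$profiles, counts = ct, perm = perm)
  })
  write_result_json(list(n_types = types$counts$n_types,
                         n_changing = types$counts$n_changing,
                         per_type = types$counts$counts,
                         permutation = types$perm$table),
                    path("response_types.json"))
  manifest$outputs$response_types <- "response_types.json"

  write_result_json(manifest, path("manifest.json"))
  invisible(list(phases = phases, mcr = mcr, fe = fe, fe_anova = fe_anova,
                 n_speciation = nspec, ox_c3g = oxc3g, types = types,
                 manifest = manifest, out_dir = out_dir))
}
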