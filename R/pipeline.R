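# End-to-end orchestration: declarative YAML config, stage toggles with
# dependency pre-flight, deterministic TSV/JSON outputs, and
# mutational-site annotation reports.

default_config <- function() {
  list(
    seed = 1,
    i_min = 3.0,
    contact_cutoff = 4.5,
    mi_threshold = 6.5,
    pmi_distance = 5.0,
    sigma_np = 0.0072,
    identity_cluster = 0.62,
    n_permutations = 50,
    weighting = "correlation",
    entropy = "none",
    subsample = NULL,
    output_dir = "kinnet_out",
    stages = list(
      dynamics = TRUE, contacts = TRUE, network = TRUE,
      coevo = TRUE, mmgbsa = TRUE, alascan = TRUE, report = TRUE
    ),
    inputs = list(
      apo = NULL, holo = NULL, ensemble = NULL, msa = NULL,
      reference_id = NULL, annotations = NULL
    )
  )
}

#' Read a pipeline configuration
#'
#' YAML configuration merged over the package defaults, which carry the
#' standard thresholds (interaction strength `I_min` 3.0 percent, contact
#' cutoff 4.5 angstrom, MI threshold 6.5, pMI distance 5 angstrom,
#' `sigma_np` 0.0072 kcal/(mol angstrom^2)).
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  cfg
}

preflight <- function(cfg) {
  st <- cfg$stages
  ins <- cfg$inputs
  need_file <- function(p, what) {
    if (is.null(p)) abort(paste0("Stage requires input: ", what))
    if (!file.exists(p)) abort(paste0("Input file missing: ", p))
  }
  if (isTRUE(st$dynamics) || isTRUE(st$mmgbsa) || isTRUE(st$alascan)) {
    need_file(ins$ensemble, "ensemble (multi-model PDB)")
  }
  if (isTRUE(st$contacts) || isTRUE(st$network)) {
    need_file(ins$holo, "holo structure (PDB)")
  }
  if (isTRUE(st$network)) need_file(ins$apo, "apo structure (PDB)")
  if (isTRUE(st$coevo)) {
    need_file(ins$msa, "MSA (FASTA)")
    if (is.null(ins$reference_id)) {
      abort("coevo stage needs inputs$reference_id for structure mapping")
    }
  }
  invisible(cfg)
}

write_tsv_out <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(x, path)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on the configured
#' inputs, writing deterministic TSV/JSON/GraphML outputs plus a
#' `provenance.json` recording the configuration, its hash and the seed.
#' Stage dependencies are checked before any computation.
#'
#' @param config A config list from [read_pipeline_config()] or a path to a
#'   YAML file.
#' @return Invisibly, a list of result objects and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else {
    utils::modifyList(default_config(), config)
  }
  preflight(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_msg <- function(...) message(sprintf("[kinnet %s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...))
  res <- list()
  paths <- character()
  st <- cfg$stages
  ins <- cfg$inputs

  holo <- if (!is.null(ins$holo)) read_pdb(ins$holo) else NULL
  apo <- if (!is.null(ins$apo)) read_pdb(ins$apo) else NULL
  ens <- if (!is.null(ins$ensemble)) read_pdb(ins$ensemble) else NULL
  if (!is.null(ens) && !inherits(ens, "kin_ensemble")) {
    abort("inputs$ensemble must be a multi-model PDB")
  }

  corr <- NULL
  if (isTRUE(st$dynamics)) {
    log_msg("dynamics: superposition, B-factors, PCA, correlations")
    ens_fit <- superpose(ens)
    bf <- compute_bfactors(ens_fit)
    corr <- cross_correlation(ens_fit)
    pc <- pca_modes(ens_fit)
    res$bfactors <- bf
    res$correlation <- corr
    res$pca <- pc
    paths <- c(
      paths,
      write_tsv_out(bf, cfg$output_dir, "bfactors.tsv"),
      write_matrix_tsv(corr, file.path(cfg$output_dir, "correlation.tsv")),
      write_tsv_out(tidy(pc), cfg$output_dir, "mobility.tsv")
    )
    ens <- ens_fit
  }

  if (isTRUE(st$contacts)) {
    log_msg("contacts: ligand contact profile, SASA, RSA")
    lc <- ensemble_ligand_contacts(if (!is.null(ens)) ens else holo,
      cutoff = cfg$contact_cutoff
    )
    sp <- sasa(holo)
    rs <- rsa(sp)
    res$ligand_contacts <- lc
    res$rsa <- rs
    paths <- c(
      paths,
      write_tsv_out(lc, cfg$output_dir, "ligand_contacts.tsv"),
      write_tsv_out(sp$residues, cfg$output_dir, "sasa_residues.tsv"),
      write_tsv_out(rs, cfg$output_dir, "rsa.tsv")
    )
  }

  if (isTRUE(st$network)) {
    log_msg("network: interaction graphs and betweenness centrality")
    weighting <- cfg$weighting
    if (weighting == "correlation" && is.null(corr)) {
      weighting <- "uniform"
      log_msg("no correlation matrix available; falling back to uniform weights")
    }
    norm <- normalization_factors(list(apo, holo))
    g_apo <- build_graph(apo,
      correlation = corr, norm = norm, i_min = cfg$i_min,
      weighting = weighting, cutoff = cfg$contact_cutoff
    )
    lc <- res$ligand_contacts
    g_holo <- build_graph(holo,
      correlation = corr, norm = norm, i_min = cfg$i_min,
      weighting = weighting, ligand_contacts = lc,
      cutoff = cfg$contact_cutoff
    )
    cb_apo <- betweenness_centrality(g_apo)
    cb_holo <- betweenness_centrality(g_holo)
    dc <- delta_centrality(cb_apo, cb_holo)
    res$graph_apo <- g_apo
    res$graph_holo <- g_holo
    res$centrality_apo <- cb_apo
    res$centrality_holo <- cb_holo
    res$delta_centrality <- dc
    paths <- c(
      paths,
      write_tsv_out(as_tibble(cb_apo), cfg$output_dir, "centrality_apo.tsv"),
      write_tsv_out(as_tibble(cb_holo), cfg$output_dir, "centrality_holo.tsv"),
      write_tsv_out(dc, cfg$output_dir, "delta_centrality.tsv"),
      write_graph_file(g_holo, file.path(cfg$output_dir, "graph_holo.graphml"))
    )
    if (!is.null(res$bfactors) && !is.null(res$rsa)) {
      jp <- joint_profiles(cb_holo, res$bfactors, res$rsa)
      res$joint <- jp
      paths <- c(paths, write_tsv_out(jp, cfg$output_dir, "joint_profiles.tsv"))
    }
  }

  if (isTRUE(st$coevo)) {
    log_msg("coevolution: MI, z-scores, KL, cMI, pMI")
    msa <- read_msa(ins$msa, reference_id = ins$reference_id)
    mi <- mi_matrix(msa)
    z <- mi_zscore(mi, msa,
      n_permutations = cfg$n_permutations,
      seed = cfg$seed
    )
    kl <- kl_conservation(msa)
    cm <- cmi(mi, z, t = cfg$mi_threshold, scale = "z")
    mapping <- map_msa_to_structure(msa, if (!is.null(apo)) apo else holo)
    pm <- pmi(cm, if (!is.null(apo)) apo else holo, mapping,
      distance = cfg$pmi_distance
    )
    circ <- export_circular(mi, z, kl, cm, pm, mapping,
      t = cfg$mi_threshold,
      path = file.path(cfg$output_dir, "circular")
    )
    res$mi <- mi
    res$mi_z <- z
    res$coevo_profile <- mapping |>
      left_join(kl, by = "column") |>
      left_join(cm, by = "column") |>
      left_join(pm |> select("column", "pmi"), by = "column")
    paths <- c(
      paths,
      write_matrix_tsv(mi, file.path(cfg$output_dir, "mi.tsv")),
      write_matrix_tsv(z, file.path(cfg$output_dir, "mi_z.tsv")),
      write_tsv_out(res$coevo_profile, cfg$output_dir, "coevo_profile.tsv")
    )
  }

  if (isTRUE(st$mmgbsa)) {
    log_msg("mmgbsa: binding free energy over %d frames", n_frames(ens))
    params <- toy_params(sigma_np = cfg$sigma_np)
    mg <- mmgbsa(ens,
      params = params, entropy = cfg$entropy,
      subsample = cfg$subsample
    )
    res$mmgbsa <- mg
    paths <- c(
      paths,
      write_tsv_out(tidy(mg), cfg$output_dir, "mmgbsa_frames.tsv")
    )
    jsonlite::write_json(
      glance(mg),
      file.path(cfg$output_dir, "mmgbsa.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA
    )
    paths <- c(paths, file.path(cfg$output_dir, "mmgbsa.json"))
  }

  if (isTRUE(st$alascan)) {
    log_msg("alanine scan")
    params <- toy_params(sigma_np = cfg$sigma_np)
    scan_res <- if (!is.null(cfg$scan_residues)) unlist(cfg$scan_residues) else NULL
    as_tbl <- alanine_scan(ens,
      params = params, residues = scan_res,
      subsample = cfg$subsample
    )
    res$alascan <- as_tbl
    paths <- c(paths, write_tsv_out(as_tibble(as_tbl), cfg$output_dir, "alascan.tsv"))
  }

  if (isTRUE(st$report) && !is.null(res$centrality_holo)) {
    ann <- if (!is.null(ins$annotations)) {
      readr::read_tsv(ins$annotations, show_col_types = FALSE)
    } else {
      NULL
    }
    rep <- annotate_profile(res$centrality_holo, ann,
      rsa_profile = res$rsa,
      bfactors = res$bfactors
    )
    res$report <- rep
    paths <- c(
      paths,
      write_tsv_out(rep$profile, cfg$output_dir, "report_profile.tsv")
    )
    if (!is.null(rep$summary)) {
      paths <- c(
        paths,
        write_tsv_out(rep$summary, cfg$output_dir, "report_summary.tsv")
      )
    }
  }

  prov <- list(
    config = cfg[setdiff(names(cfg), "stages")],
    stages = cfg$stages,
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  json_path <- file.path(cfg$output_dir, "provenance.json")
  jsonlite::write_json(
    prov[c("config", "stages", "config_hash", "seed")],
    json_path,
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  log_msg("done: %d outputs in %s", length(paths), cfg$output_dir)
  invisible(c(res, list(paths = c(paths, json_path), config = cfg)))
}

#' Merge a centrality profile with mutational-site annotations
#'
#' Per-residue annotation classes (`highly_resistant`, `moderately_resistant`,
#' `sensitive`) are joined onto the centrality profile; duplicate annotation
#' rows are deduplicated with a warning and unresolvable keys are reported,
#' not silently dropped. A class-wise summary (median centrality per
#' resistance class) accompanies the merged table.
#'
#' @param centrality A `kin_centrality`.
#' @param annotation Tibble with `key`, `class` and optionally `drug`;
#'   `NULL` passes the profile through.
#' @param rsa_profile,bfactors Optional per-residue tables joined onto the
#'   report.
#' @return List with `profile`, `summary` (or `NULL`), and `unresolved`
#'   keys.
#' @export
annotate_profile <- function(centrality, annotation = NULL,
                             rsa_profile = NULL, bfactors = NULL) {
  prof <- as_tibble(centrality) |> filter(!.data$is_ligand)
  if (!is.null(rsa_profile)) {
    prof <- prof |> left_join(rsa_profile |> select("key", "rsa"), by = "key")
  }
  if (!is.null(bfactors)) {
    prof <- prof |> left_join(bfactors |> select("key", "bfactor"), by = "key")
  }
  if (is.null(annotation) || nrow(annotation) == 0) {
    return(list(profile = prof, summary = NULL, unresolved = character()))
  }
  annotation <- as_tibble(annotation)
  allowed <- c("highly_resistant", "moderately_resistant", "sensitive")
  bad <- setdiff(unique(annotation$class), allowed)
  if (length(bad) > 0) {
    abort(paste0(
      "Annotation class(es) outside the closed set: ",
      paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(annotation$key) > 0) {
    warn("Duplicate annotation rows deduplicated")
    annotation <- annotation |> distinct(.data$key, .keep_all = TRUE)
  }
  unresolved <- setdiff(annotation$key, prof$key)
  if (length(unresolved) > 0) {
    warn(paste0(
      "Annotation key(s) not resolvable against the structure: ",
      paste(unresolved, collapse = ", ")
    ))
  }
  prof <- prof |> left_join(annotation, by = "key")
  summary <- prof |>
    filter(!is.na(.data$class)) |>
    group_by(.data$class) |>
    summarise(
      n = dplyr::n(),
      median_betweenness = stats::median(.data$betweenness),
      .groups = "drop"
    )
  list(profile = prof, summary = summary, unresolved = unresolved)
}

#' Write a ready-to-run synthetic demonstration configuration
#'
#' Generates a small apo/holo pair, a mode-driven ensemble of the holo
#' complex, a planted-coevolution alignment whose reference row matches the
#' apo sequence, and an annotation table, then writes a matching YAML
#' config. Running [run_pipeline()] on the returned path exercises every
#' stage.
#'
#' @param dir Output directory for inputs and results.
#' @param seed Integer seed controlling every generator.
#' @param n_residues,n_frames,n_sequences Problem sizes.
#' @return Path to the written YAML config.
#' @export
demo_config <- function(dir, seed = 1, n_residues = 24, n_frames = 40,
                        n_sequences = 400) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pocket <- c(3, n_residues - 2)
  cx <- gen_complex(complex_spec(n_residues, pocket, ligand_atoms = 4, seed = seed))
  first_internal <- anm_modes(cx$holo)$n_rigid + 1
  ens <- gen_ensemble(cx$holo, n_frames,
    mode_spectrum = list(mode = first_internal, amplitude = 0.6),
    noise_sd = 0.15, seed = seed + 1
  )
  write_pdb(cx$apo, file.path(dir, "apo.pdb"))
  write_pdb(cx$holo, file.path(dir, "holo.pdb"))
  write_pdb(ens, file.path(dir, "ensemble.pdb"))
  rt <- residue_table(cx$apo)
  ref_seq <- unname(AA_THREE_TO_ONE[rt$res_type])
  msa <- gen_msa(msa_spec(
    n_sequences, n_residues,
    conserved_columns = list(list(col = 5, res = ref_seq[5], p = 0.95)),
    coevolving_pairs = list(
      list(col_a = 2, col_b = 9, coupling = 0.9)
    ),
    seed = seed + 2
  ))
  # make the first row the structure-matching reference
  msa$matrix[1, ] <- ref_seq
  msa$ids[1] <- "reference"
  write_msa_fasta(msa, file.path(dir, "msa.fasta"))
  ann <- tibble(
    key = rt$key[pocket],
    class = c("highly_resistant", "sensitive")[seq_along(pocket)],
    drug = "synthetic"
  )
  readr::write_tsv(ann, file.path(dir, "annotations.tsv"))
  cfg <- list(
    seed = seed,
    output_dir = file.path(dir, "out"),
    n_permutations = 30,
    subsample = 8,
    scan_residues = as.list(rt$key[pocket]),
    inputs = list(
      apo = file.path(dir, "apo.pdb"),
      holo = file.path(dir, "holo.pdb"),
      ensemble = file.path(dir, "ensemble.pdb"),
      msa = file.path(dir, "msa.fasta"),
      reference_id = "reference",
      annotations = file.path(dir, "annotations.tsv")
    )
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
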