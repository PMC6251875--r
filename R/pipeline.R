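# End-to-end orchestration over synthetic or user-supplied inputs: simulate ->
# descriptors -> poses -> QSAR -> correlation, with seeded reproducibility and
# a provenance report.

#' Assign crude fixture partial charges
#'
#' A deliberately simple electronegativity-flavoured charge model for test
#' fixtures and demos (O -0.40, N -0.30, H on O/N +0.40/+0.30, H on C +0.05,
#' remainder balanced over carbons so the sum matches the formal charge). Not
#' a substitute for a real charge model; real applications should supply
#' charges from whatever model produced their structures.
#'
#' @param mol a [molecule].
#' @return the molecule with `charge` filled in.
#' @export
assign_simple_charges <- function(mol) {
  el <- mol$atoms$element
  q <- numeric(length(el))
  q[el == "O"] <- -0.40
  q[el == "N"] <- -0.30
  hl <- attached_hydrogens(mol)
  for (k in seq_along(el)) {
    for (h in hl[[k]]) {
      q[h] <- switch(el[k], O = 0.40, N = 0.30, 0.05)
    }
  }
  resid_q <- mol$formal_charge - sum(q)
  carbons <- which(el == "C")
  sink <- if (length(carbons)) carbons else seq_along(el)
  q[sink] <- q[sink] + resid_q / length(sink)
  mol$atoms$charge <- q
  mol
}

# schematic per-substrate demo molecule, varied by class and index
demo_substrate_molecule <- function(class, i) {
  m <- switch(class,
    phenol = phenol_like_molecule(methoxy = i %% 2 == 0),
    gen_toy_molecule(if (i %% 2 == 0) "ring" else "linear_chain",
                     n_atoms = 4 + i %% 4, separation = 1.5)
  )
  # per-substrate size scaling keeps the schematic series non-degenerate
  scale <- 0.90 + 0.025 * (i %% 9)
  m$atoms$x <- m$atoms$x * scale
  m$atoms$y <- m$atoms$y * scale
  m$atoms$z <- m$atoms$z * scale
  assign_simple_charges(m)
}

#' Compute the full descriptor record of one molecule
#'
#' Convenience wrapper collecting every in-package descriptor (surface,
#' shape, partition, logP/logS analogues, acceptor count, ESP extrema) into a
#' one-row tibble with the canonical column names used by the QSAR module.
#'
#' @param mol a [molecule] (charges required for the ESP columns).
#' @param probe_radius,n_points,grid_spacing numerical parameters of the
#'   surface computations.
#' @return one-row tibble: `SASA`, `volume`, `glob`, `Vol/SASA`, `FISA`,
#'   `PISA`, `QPlogPo/w`, `QPlogS`, `accptHB`, `ESP_max`, `ESP_min`.
#' @export
descriptor_record <- function(mol, probe_radius = 1.4, n_points = 480L,
                              grid_spacing = 0.25) {
  sh <- shape_descriptors(mol, probe_radius, n_points, grid_spacing)
  sp <- surface_partition(mol, probe_radius, n_points)
  ll <- logp_logs(mol)
  esp <- if (!all(is.na(mol$atoms$charge))) {
    esp_extrema(mol, probe_radius, n_points)
  } else tibble::tibble(esp_max = NA_real_, esp_min = NA_real_)
  tibble::tibble(
    SASA = sh$sasa, volume = sh$volume, glob = sh$glob,
    `Vol/SASA` = sh$vol_sasa, FISA = sp$fisa, PISA = sp$pisa,
    `QPlogPo/w` = ll$logp, QPlogS = ll$logs,
    accptHB = count_hb_acceptors(mol),
    ESP_max = esp$esp_max, ESP_min = esp$esp_min
  )
}

validate_run_config <- function(config) {
  defaults <- list(
    seed = 1L, out_dir = "lacqsar_run", dataset_shape = "B",
    max_k = 3L, criterion = "q2", n_flexibility = c(0, 4, 8, 12, 16, 20),
    donor_threshold = 5.0, activity_csv = NULL, response = NULL
  )
  config <- utils::modifyList(defaults, config)
  if (!is.null(config$activity_csv)) {
    if (!file.exists(config$activity_csv)) {
      stop("activity_csv does not exist: ", config$activity_csv,
           call. = FALSE)
    }
    act <- utils::read.csv(config$activity_csv, check.names = FALSE)
    if (is.null(config$response) || !config$response %in% names(act)) {
      stop("config$response must name a column of activity_csv",
           call. = FALSE)
    }
  }
  config
}

#' Run the full analysis pipeline
#'
#' Stages, in the order of the underlying workflow: (1) simulate or load the
#' activity table; (2) build per-substrate molecules and compute the
#' descriptor table (plus electronic descriptors from a generated
#' orbital-energy table); (3) construct poses, fingerprint them and call
#' active conformations; (4) normalize and run the exhaustive QSAR subset
#' search, saving the best model; (5) generate a binding-energy score table
#' and run the correlation scan. Every stage output is written to
#' `config$out_dir` as CSV/JSON; the run report records the seed and content
#' hashes so reruns can be verified bit-identical (timestamps excepted).
#'
#' @param config named list or path to a YAML file. Recognised fields:
#'   `seed`, `out_dir`, `dataset_shape` (`"A"`/`"B"`/`"C"`),
#'   `activity_csv` + `response` (to use a real table instead of a simulated
#'   one), `max_k`, `criterion`, `donor_threshold`.
#' @return the run report (named list), invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  seed <- as.integer(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$out_dir, f)
  written <- character(0)
  emit <- function(df, f) {
    utils::write.csv(df, outfile(f), row.names = FALSE)
    written <<- c(written, f)
  }

  # stage 1: activity table
  act <- if (!is.null(config$activity_csv)) {
    tibble::as_tibble(utils::read.csv(config$activity_csv,
                                      check.names = FALSE))
  } else {
    gen_activity_table(config$dataset_shape, seed = seed)
  }
  response_col <- config$response %||%
    (if (all(is.na(act$km_um))) "log_activity" else "pkm")
  if (is.null(config$activity_csv)) {
    act[[response_col]] <- if (response_col == "pkm") {
      km_to_pkm(act$km_um)
    } else activity_to_log(act$relative_activity)
  }
  emit(act, "activity.csv")

  # stage 2: descriptor table
  mols <- purrr::imap(act$class %||% rep("phenol", nrow(act)),
                      function(cl, i) demo_substrate_molecule(cl, i))
  desc <- purrr::map_dfr(mols, descriptor_record)
  orb <- gen_orbital_table(nrow(act), seed = seed + 1)
  elec <- koopmans_descriptors(orb[c("e_homo_ha", "e_lumo_ha")])
  table <- dplyr::bind_cols(
    act[c("id", response_col)], desc,
    tibble::tibble(IP = elec$ip, EA = elec$ea, gap = elec$gap)
  )
  emit(table, "descriptor_table.csv")

  # stage 3: poses and fingerprints
  dists <- with_seed(seed + 2, stats::runif(nrow(act), 3.0, 7.0))
  fps <- purrr::map2_dfr(dists, act$id, function(d, id) {
    cx <- gen_synthetic_pose(d)
    fp <- build_fingerprint(cx, active_threshold = config$donor_threshold)
    call <- attr(fp, "active_call")
    tibble::tibble(id = id, donor_distance = call$distance_to_his,
                   is_active = call$is_active, n_contacts = nrow(fp))
  })
  emit(fps, "fingerprints.csv")

  # stage 4: QSAR subset search on the computed descriptors
  cand <- names(table)[vapply(table, is.numeric, logical(1))]
  cand <- setdiff(cand, c(response_col, "ESP_min", "gap"))
  cand <- cand[vapply(table[cand], function(x) {
    all(is.finite(x)) && stats::sd(x) > 0
  }, logical(1))]
  search <- subset_search(table, response_col, candidates = cand,
                          max_k = config$max_k, criterion = config$criterion)
  emit(search[setdiff(names(search), "model")], "qsar_leaderboard.csv")
  best <- search$model[[1]]
  write_qsar_model(best, outfile("best_model.json"),
                   data_hash = rlang::hash(table))
  written <- c(written, "best_model.json")

  # stage 5: synthetic binding-energy table + correlation scan
  flex <- config$n_flexibility
  y <- table[[response_col]]
  scores <- with_seed(seed + 3, {
    s <- tibble::tibble(id = act$id)
    for (fx in flex) {
      s[[paste0("mmgbsa_", fx, "A")]] <-
        -y + stats::rnorm(length(y), 0, 0.3 + 0.15 * fx)
    }
    s$docking <- with_seed(seed + 4, stats::rnorm(length(y)))
    s
  })
  emit(scores, "scores.csv")
  scan <- correlation_scan(scores, act |>
                             dplyr::mutate(!!response_col := y),
                           response = response_col)
  emit(scan, "correlation_scan.csv")

  report <- list(
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    response = response_col,
    outputs = written,
    hashes = stats::setNames(
      lapply(written, function(f) rlang::hash(readLines(outfile(f)))),
      written),
    best_model = search$descriptors[1],
    best_q2 = search$q_squared[1],
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(report, outfile("run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
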