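#' Experiment configuration for the end-to-end pipeline
#'
#' Describes a full synthetic experiment: cohort sizes, phantom parameter
#' ranges, defect and attenuation models, training configuration, and the
#' master seed from which every per-case seed is derived by a fixed
#' counter scheme (logged in the manifest).
#'
#' @param n_train,n_test cases used for model training / held-out testing.
#' @param states acquisition states simulated per case.
#' @param matrix_size phantom matrix size (desk default 64).
#' @param baseline_range uniform range of per-case baseline uptake.
#' @param defect_prob probability that a case carries a true defect.
#' @param defect_severity uniform range of defect severity.
#' @param attenuation an [attenuation_spec()] or `NULL` to disable.
#' @param noise_scale phantom noise scale (see [phantom_config()]).
#' @param train a [train_config()].
#' @param seed master seed.
#' @param out_dir output directory for [run_experiment()].
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(n_train = 8L, n_test = 4L,
                              states = c("stress", "rest"),
                              matrix_size = 64L,
                              baseline_range = c(76, 84),
                              defect_prob = 0.5,
                              defect_severity = c(0.35, 0.7),
                              attenuation = attenuation_spec(),
                              noise_scale = 0.5,
                              train = train_config("desk"),
                              seed = 1L, out_dir = tempfile("acspect_run_")) {
  stopifnot(n_train >= 1, n_test >= 1, all(states %in% c("stress", "rest")))
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 states = states, matrix_size = as.integer(matrix_size),
                 baseline_range = baseline_range, defect_prob = defect_prob,
                 defect_severity = defect_severity, attenuation = attenuation,
                 noise_scale = noise_scale, train = train,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

# Fixed counter scheme deriving per-case seeds from the master seed.
case_seed <- function(master, i) (as.integer(master) %% 100000L) * 10007L + i * 101L

sample_case <- function(config, i, role) {
  set.seed(case_seed(config$seed, i))
  n <- config$matrix_size
  pc <- phantom_config(
    matrix_size = n,
    ring_center = (n + 1) / 2 + stats::runif(2, -2, 2),
    endo_radius_mm = 17 * stats::runif(1, 0.92, 1.08),
    epi_radius_mm = 24 * stats::runif(1, 0.92, 1.08),
    baseline_uptake = stats::runif(1, config$baseline_range[1], config$baseline_range[2]),
    noise_scale = config$noise_scale,
    seed = case_seed(config$seed, i) + 1L)
  defects <- list()
  if (stats::runif(1) < config$defect_prob) {
    terr <- territory_map_default()[[sample(3L, 1L)]]
    segs <- sample(terr, sample(1:2, 1L))
    sev <- stats::runif(1, config$defect_severity[1], config$defect_severity[2])
    defects <- list(defect_spec(segs, sev,
                                state = sample(c("stress", "both"), 1L)))
  }
  list(id = sprintf("%s%02d", role, i), config = pc, defects = defects)
}

simulate_case <- function(case, config) {
  out <- list()
  for (st in config$states) {
    pair <- generate_patient_pair(case$config, case$defects,
                                  attenuation = config$attenuation,
                                  seed = case$config$seed +
                                    match(st, c("stress", "rest")),
                                  state = st)
    out[[st]] <- pair
  }
  out
}

#' Run the full synthetic experiment
#'
#' Simulates the cohort, preprocesses every SPECT/PET pair onto a common
#' geometry, trains one translation model per state on the training cases,
#' translates the held-out test SPECT stacks, and quantifies the
#' correction (similarity metrics, 17-segment tables, scores, territory
#' ROC). All tables are written as CSV under `config$out_dir`, image
#' stacks as 8-bit PGM slices, and a JSON manifest captures seeds,
#' configuration and file checksums. Figures (score-error bullseye, joint
#' histograms) are regenerated from the CSV tables.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return invisibly, a report bundle: `models`, `segment_tables`,
#'   `similarity`, `scores`, `roc`, `manifest`.
#' @export
run_experiment <- function(config, verbose = interactive()) {
  stopifnot(inherits(config, "experiment_config"))
  dirs <- file.path(config$out_dir,
                    c("phantoms", "preprocessed", "translated", "reports"))
  names(dirs) <- basename(dirs)
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  roles <- c(rep("train", config$n_train), rep("test", config$n_test))
  cases <- lapply(seq_along(roles), function(i)
    sample_case(config, i, roles[i]))

  # ---- stage 1: simulate ---------------------------------------------------
  say("simulating %d cases ...", length(cases))
  sim <- lapply(seq_along(cases), function(i) {
    s <- simulate_case(cases[[i]], config)
    for (st in names(s)) {
      write_stack_pgm(s[[st]]$spect, dirs["phantoms"], cases[[i]]$id)
      write_stack_pgm(s[[st]]$pet, dirs["phantoms"], cases[[i]]$id)
      write_truth_csv(s[[st]]$truth,
                      file.path(dirs["phantoms"],
                                sprintf("%s_%s_truth.csv", cases[[i]]$id, st)))
    }
    s
  })

  # ---- stage 2: preprocess -------------------------------------------------
  say("preprocessing ...")
  prep <- lapply(seq_along(sim), function(i) {
    lapply(sim[[i]], function(pair) {
      pp <- preprocess_pair(pair$spect, pair$pet)
      for (s in pp) write_stack_pgm(s, dirs["preprocessed"], cases[[i]]$id)
      pp
    })
  })

  # ---- stage 3: train (one model per state) --------------------------------
  is_train <- roles == "train"
  models <- list()
  for (st in config$states) {
    say("training %s model ...", st)
    pool_S <- lapply(prep[is_train], function(p) p[[st]]$spect)
    pool_P <- lapply(prep[is_train], function(p) p[[st]]$pet)
    models[[st]] <- train_translation(pool_S, pool_P, config$train)
    utils::write.csv(models[[st]]$loss_trace,
                     file.path(dirs["reports"], sprintf("loss_%s.csv", st)),
                     row.names = FALSE)
  }

  # ---- stage 4: translate test cases ---------------------------------------
  say("translating test cases ...")
  test_idx <- which(!is_train)
  translated <- lapply(test_idx, function(i) {
    lapply(config$states, function(st) {
      spt <- translate_stack(models[[st]], prep[[i]][[st]]$spect)
      write_stack_pgm(spt, dirs["translated"], cases[[i]]$id)
      spt
    }) |> stats::setNames(config$states)
  })

  # ---- stage 5: quantify ---------------------------------------------------
  say("quantifying ...")
  seg_rows <- list(); sim_rows <- list()
  for (j in seq_along(test_idx)) {
    i <- test_idx[j]
    for (st in config$states) {
      pp <- prep[[i]][[st]]; spt <- translated[[j]][[st]]
      rep_ <- similarity_report(pp$pet, pp$spect, spt)
      rep_$case <- cases[[i]]$id; rep_$state <- st
      sim_rows[[length(sim_rows) + 1L]] <- rep_
      ctr <- lv_center(pp$pet)
      for (m in c("pet", "spect", "spect_spt")) {
        stk <- switch(m, pet = pp$pet, spect = pp$spect, spect_spt = spt)
        tb <- segment_table(stk, center = ctr)
        tb$case <- cases[[i]]$id; tb$state <- st; tb$method <- m
        seg_rows[[length(seg_rows) + 1L]] <- tb
      }
    }
  }
  segments <- do.call(rbind, seg_rows)
  similarity <- do.call(rbind, sim_rows)
  utils::write.csv(segments, file.path(dirs["reports"], "segment_tables.csv"),
                   row.names = FALSE)
  utils::write.csv(similarity, file.path(dirs["reports"], "similarity.csv"),
                   row.names = FALSE)

  # ---- stage 6: score + ROC ------------------------------------------------
  say("scoring ...")
  scores <- list(); roc <- NULL
  both_states <- all(c("stress", "rest") %in% config$states)
  if (both_states) {
    get_tab <- function(case, st, m)
      segments[segments$case == case & segments$state == st &
                 segments$method == m, c("segment", "value")]
    ids <- vapply(cases[test_idx], `[[`, "", "id")
    for (id in ids)
      for (m in c("pet", "spect", "spect_spt"))
        scores[[paste(id, m, sep = ".")]] <-
          score_case(get_tab(id, "stress", m), get_tab(id, "rest", m))
    score_df <- do.call(rbind, lapply(names(scores), function(k) {
      sc <- scores[[k]]
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      data.frame(case = parts[1], method = parts[2],
                 segment = 1:17, stress = sc$stress_scores,
                 rest = sc$rest_scores, diff = sc$diff_scores,
                 sss = sc$sss, srs = sc$srs, sds = sc$sds)
    }))
    utils::write.csv(score_df, file.path(dirs["reports"], "scores.csv"),
                     row.names = FALSE)
    roc_rows <- list()
    for (terr in c("RCA", "LAD", "LCX")) {
      truth <- vapply(ids, function(id)
        defect_presence(scores[[paste(id, "pet", sep = ".")]], terr), TRUE)
      for (m in c("spect", "spect_spt")) {
        idx <- vapply(ids, function(id)
          sum(scores[[paste(id, m, sep = ".")]]$territory_scores[terr, ]), 0)
        if (length(unique(truth)) < 2) {
          roc_rows[[paste(terr, m)]] <- data.frame(
            territory = terr, method = m, auc = NA_real_,
            sensitivity = NA_real_, specificity = NA_real_,
            threshold = NA_real_, note = "single-class truth")
        } else {
          r <- roc_defect_detection(truth, idx)
          roc_rows[[paste(terr, m)]] <- data.frame(
            territory = terr, method = m, auc = r$auc,
            sensitivity = r$sensitivity, specificity = r$specificity,
            threshold = r$threshold, note = "")
        }
      }
    }
    roc <- do.call(rbind, roc_rows)
    utils::write.csv(roc, file.path(dirs["reports"], "roc.csv"),
                     row.names = FALSE)
    # mean stress score error polar maps, regenerated from the scores CSV
    sdf <- utils::read.csv(file.path(dirs["reports"], "scores.csv"))
    for (m in c("spect", "spect_spt")) {
      err <- vapply(1:17, function(s)
        mean(sdf$stress[sdf$method == m & sdf$segment == s]) -
          mean(sdf$stress[sdf$method == "pet" & sdf$segment == s]), 0)
      plot_bullseye(err, file.path(dirs["reports"],
                                   sprintf("score_error_%s.png", m)),
                    limits = c(-2, 2),
                    main = sprintf("mean stress score error: %s - pet", m))
    }
  }

  manifest <- list(
    master_seed = config$seed,
    case_seeds = stats::setNames(
      vapply(seq_along(cases), function(i) case_seed(config$seed, i), 0L),
      vapply(cases, `[[`, "", "id")),
    seed_scheme = "case_seed(master, i) = (master %% 1e5) * 10007 + 101 * i",
    states = config$states,
    train_config = unclass(config$train),
    checksums = lapply(dirs, function(d) {
      f <- sort(list.files(d, full.names = TRUE))
      as.list(stats::setNames(unname(tools::md5sum(f)), basename(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cases = cases, models = models, segment_tables = segments,
                 similarity = similarity, scores = scores, roc = roc,
                 manifest = manifest, out_dir = config$out_dir))
}
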