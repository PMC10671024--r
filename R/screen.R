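#' Default thresholds of the screening pipeline
#'
#' Central registry of every tunable threshold; all downstream
#' functions take this object so that a screen logs exactly the values
#' it used.
#'
#' @param cutoff_A heavy-atom interface contact cutoff (A, default 5).
#' @param orientation_tol_deg topology rule (i) tolerance (default 30).
#' @param layer_tol_A topology rule (ii) midplane offset tolerance
#'   (A, default 8).
#' @param overlap_min minimum `frac_of_dimer` for a "significantly
#'   overlapped" interface (default 0.25).
#' @param delta_close "lower than or close to" BFE allowance
#'   (kcal/mol, default 15).
#' @param delta_keep retention window above the most stable model
#'   (kcal/mol, default 15).
#' @param qualifier_frac dominance fraction for E/M/I qualifiers
#'   (default 0.6).
#' @param clash_cutoff_A heavy-atom clash threshold (A, default 2).
#' @param half_thickness_A membrane slab half-thickness (A, default 15).
#' @return list of class `screen_params`.
#' @export
screen_params <- function(cutoff_A = 5, orientation_tol_deg = 30,
                          layer_tol_A = 8, overlap_min = 0.25,
                          delta_close = 15, delta_keep = 15,
                          qualifier_frac = 0.6, clash_cutoff_A = 2,
                          half_thickness_A = 15) {
  structure(list(cutoff_A = cutoff_A,
                 orientation_tol_deg = orientation_tol_deg,
                 layer_tol_A = layer_tol_A, overlap_min = overlap_min,
                 delta_close = delta_close, delta_keep = delta_keep,
                 qualifier_frac = qualifier_frac,
                 clash_cutoff_A = clash_cutoff_A,
                 half_thickness_A = half_thickness_A),
            class = "screen_params")
}

jaccard_set <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Select the most stable models of a complex group
#'
#' Keeps the model with the lowest (most negative) mean BFE; keeps in
#' addition any model within `delta_keep` kcal/mol of the best whose
#' subject interface helix set is distinct from every already-kept
#' model (helix-set Jaccard < `distinct_max_jaccard`); at most
#' `max_keep` models are retained. Comparably stable models with
#' distinct interfaces are thus all analysed, reflecting the diversity
#' of receptor interaction modes.
#'
#' @param models either a data.frame with columns `bfe_mean` and
#'   `interface` (a TM interface string, parsed for the helix set), or
#'   a list of `complex_model`s carrying BFEs (helix sets are then
#'   computed from the structures).
#' @param delta_keep retention window (kcal/mol, default 15).
#' @param max_keep maximum number retained (default 3).
#' @param distinct_max_jaccard helix-set distinctness bound
#'   (default 0.5).
#' @param params thresholds used when helix sets are computed from
#'   structures.
#' @return integer indices of the kept models (ascending).
#' @export
select_most_stable <- function(models, delta_keep = 15, max_keep = 3,
                               distinct_max_jaccard = 0.5,
                               params = screen_params()) {
  if (is.data.frame(models)) {
    if (nrow(models) == 0L) stop("no models to select from")
    means <- models$bfe_mean
    sets <- lapply(models$interface, interface_helix_set)
  } else if (is.list(models)) {
    if (length(models) == 0L) stop("no models to select from")
    means <- vapply(models, function(m) {
      if (is.null(m$bfe)) stop("model without a BFE")
      m$bfe$mean
    }, numeric(1))
    sets <- lapply(models, function(m) {
      helix_contributions(m, cutoff_A = params$cutoff_A)$helix
    })
  } else stop("models must be a data.frame or a list of complex models")

  ord <- order(means, seq_along(means))
  kept <- ord[1]
  best <- means[ord[1]]
  for (i in ord[-1]) {
    if (length(kept) >= max_keep) break
    if (means[i] > best + delta_keep) break
    distinct <- all(vapply(kept, function(k) {
      jaccard_set(sets[[i]], sets[[k]]) < distinct_max_jaccard
    }, logical(1)))
    if (distinct) kept <- c(kept, i)
  }
  sort(kept)
}

#' Read a binding free energy table
#'
#' TSV/CSV with columns `label`, `mean`, `sem` (kcal/mol), one row per
#' model designation. BFEs are pipeline inputs; the package never
#' computes them.
#'
#' @param path file path; separator inferred from the extension.
#' @return data.frame with columns `label`, `mean`, `sem`.
#' @export
read_bfe_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  bf <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("label", "mean", "sem")
  if (!all(req %in% names(bf))) {
    stop("BFE table must have columns: ", paste(req, collapse = ", "))
  }
  bf[, req]
}

#' Read a screen configuration from YAML or JSON
#'
#' Relative model/BFE paths are resolved against the config file's
#' directory.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return config list for [run_screen()].
#' @export
read_screen_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  # tolerate column-wise (named lists of vectors) and row-wise
  # (lists of records) table encodings from JSON/YAML
  to_df <- function(x) {
    if (is.data.frame(x)) return(x)
    if (!is.null(names(x))) {
      return(as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(x, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  cfg$groups <- lapply(cfg$groups, function(g) {
    g$models <- to_df(g$models)
    g$models$path <- fix(g$models$path)
    if (is.character(g$bfe) && length(g$bfe) == 1L) g$bfe <- fix(g$bfe)
    else g$bfe <- to_df(g$bfe)
    if (!is.null(g$energy)) g$energy <- lapply(g$energy, function(p) fix(unlist(p)))
    g
  })
  if (!is.null(cfg$blocking)) cfg$blocking <- to_df(cfg$blocking)
  cfg
}

load_group_model <- function(group, label) {
  row <- group$models[group$models$label == label, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("model '", label, "' not found in group '", group$name, "'")
  }
  cm <- read_complex_pdb(row$path)
  bf <- if (is.character(group$bfe)) read_bfe_table(group$bfe) else group$bfe
  hit <- bf[bf$label == label, , drop = FALSE]
  if (nrow(hit) == 1L) cm$bfe <- new_binding_energy(hit$mean, hit$sem)
  cm
}

#' Run the full model-triage screen
#'
#' Reproduces the triage workflow over groups of docked/predicted
#' complex models: topology-compliance filtering, interface
#' characterisation of compliant models, most-stable model selection
#' from the BFE table, optional blocking verdicts for configured
#' dimer/blocker pairs, and competition groups among selected models
#' sharing a subject. A failing group is recorded and skipped; other
#' groups continue. Deterministic given identical inputs.
#'
#' @param config list with elements:
#'   `groups`: list of groups, each with `name`, `models` (data.frame
#'   `label`, `path`; each path a PDB written by [write_complex_pdb()]
#'   with its sidecar), `bfe` (data.frame `label`, `mean`, `sem`, or a
#'   file path), and optionally `energy` (named list label -> energy
#'   CSV); `blocking` (optional data.frame `dimer_group`, `dimer_label`,
#'   `blocker_group`, `blocker_label`); `params` (optional
#'   [screen_params()]).
#' @param out_dir optional output directory; when given, writes
#'   `screen_report.tsv`, `verdicts.tsv` and `screen_report.json`.
#' @return object of class `screen_report` with `report` (one row per
#'   input model), `verdicts`, `competition`, `errors` and `params`.
#' @export
run_screen <- function(config, out_dir = NULL) {
  params <- config$params %||% screen_params()
  if (!inherits(params, "screen_params")) params <- do.call(screen_params, params)
  rows <- list(); errors <- list(); complexes <- list()

  for (g in config$groups) {
    res <- tryCatch({
      bf <- if (is.character(g$bfe)) read_bfe_table(g$bfe) else g$bfe
      grows <- lapply(seq_len(nrow(g$models)), function(i) {
        lab <- g$models$label[i]
        cm <- read_complex_pdb(g$models$path[i])
        comp <- topology_filter(cm, params)
        et <- NULL
        if (!is.null(g$energy) && !is.null(g$energy[[lab]])) {
          et <- read_energy_table(g$energy[[lab]])
        }
        istr <- if (comp$compliant) {
          interface_profile(cm, params, et)$interface_string
        } else NA_character_
        hit <- bf[bf$label == lab, , drop = FALSE]
        list(row = data.frame(
               group = g$name, label = lab, compliant = comp$compliant,
               interface = istr,
               bfe_mean = if (nrow(hit) == 1L) hit$mean else NA_real_,
               bfe_sem = if (nrow(hit) == 1L) hit$sem else NA_real_,
               selected = FALSE, stringsAsFactors = FALSE),
             cm = cm)
      })
      df <- do.call(rbind, lapply(grows, `[[`, "row"))
      elig <- which(df$compliant & !is.na(df$bfe_mean) & !is.na(df$interface))
      if (length(elig) > 0L) {
        keep <- select_most_stable(
          data.frame(bfe_mean = df$bfe_mean[elig],
                     interface = df$interface[elig]),
          delta_keep = params$delta_keep)
        df$selected[elig[keep]] <- TRUE
      }
      cms <- lapply(grows, `[[`, "cm")
      names(cms) <- df$label
      list(df = df, cms = cms)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[g$name]] <- conditionMessage(res)
    } else {
      rows[[g$name]] <- res$df
      complexes[[g$name]] <- res$cms
    }
  }
  report <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(group = character(), label = character(),
               compliant = logical(), interface = character(),
               bfe_mean = numeric(), bfe_sem = numeric(),
               selected = logical())
  rownames(report) <- NULL

  verdicts <- data.frame(
    dimer = character(), blocker = character(), frac_of_dimer = numeric(),
    jaccard = numeric(), bfe_dimer = numeric(), bfe_blocker = numeric(),
    overlap_min = numeric(), delta_close = numeric(), blocks = logical(),
    stringsAsFactors = FALSE)
  if (!is.null(config$blocking)) {
    for (i in seq_len(nrow(config$blocking))) {
      b <- config$blocking[i, ]
      v <- tryCatch({
        dg <- config$groups[[match(b$dimer_group,
                vapply(config$groups, `[[`, "", "name"))]]
        bg <- config$groups[[match(b$blocker_group,
                vapply(config$groups, `[[`, "", "name"))]]
        dimer <- load_group_model(dg, b$dimer_label)
        blocker <- load_group_model(bg, b$blocker_label)
        blocking_verdict(dimer, blocker, params)
      }, error = function(e) e)
      if (inherits(v, "error")) {
        errors[[paste0("blocking:", i)]] <- conditionMessage(v)
      } else {
        verdicts <- rbind(verdicts, data.frame(
          dimer = paste0(b$dimer_group, "/", b$dimer_label),
          blocker = paste0(b$blocker_group, "/", b$blocker_label),
          frac_of_dimer = v$overlap$frac_of_dimer,
          jaccard = v$overlap$jaccard,
          bfe_dimer = v$bfe_dimer$mean, bfe_blocker = v$bfe_blocker$mean,
          overlap_min = v$overlap_min_used, delta_close = v$delta_used,
          blocks = v$blocks, stringsAsFactors = FALSE))
      }
    }
  }

  # competition among selected models sharing an identical subject
  competition <- list()
  sel <- report[report$selected, , drop = FALSE]
  if (nrow(sel) >= 2L) {
    cms <- lapply(seq_len(nrow(sel)), function(i) {
      complexes[[sel$group[i]]][[sel$label[i]]]
    })
    ids <- paste0(sel$group, "/", sel$label)
    seqs <- vapply(cms, function(cm) cm$subject$sequence, character(1))
    for (s in unique(seqs)) {
      idx <- which(seqs == s)
      if (length(idx) < 2L) next
      grp <- competition_groups(cms[idx], params)
      for (gset in grp) {
        competition[[length(competition) + 1L]] <- ids[idx][gset]
      }
    }
  }

  out <- structure(list(report = report, verdicts = verdicts,
                        competition = competition, errors = errors,
                        params = params),
                   class = "screen_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "screen_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(verdicts, file.path(out_dir, "verdicts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(report = report, verdicts = verdicts,
           competition = competition, errors = errors,
           params = unclass(params)),
      file.path(out_dir, "screen_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  }
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>", nrow(x$report), "model rows,",
      nrow(x$verdicts), "blocking verdicts,",
      length(x$competition), "competition groups,",
      length(x$errors), "group errors\n")
  invisible(x)
}

#' Generate a complete synthetic screen fixture set
#'
#' Writes two groups of synthetic dimer models (PDB + sidecar), their
#' BFE tables, one per-residue energy table, and a ready-to-run screen
#' config: a homodimer group (three compliant poses on distinct faces
#' plus one flipped decoy) and a heterodimer group with a truncated
#' 2-TM isoform partner (two compliant poses plus one offset decoy),
#' standing in for docking/prediction outputs.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the generator.
#' @return config list (also written to `screen_config.json`).
#' @export
generate_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- build_ideal_bundle(bundle_spec(7, seed = seed), "A", "subject")
  iso <- build_ideal_bundle(bundle_spec(2, seed = seed + 2,
                                        markers = c("ALA", "GLY")),
                            "B", "isoform")

  write_model <- function(cm, file) {
    write_complex_pdb(cm, file.path(dir, file))
    file.path(dir, file)
  }
  homo <- list(
    `AF-1` = place_dimer(rec, rec, dimer_pose_spec(c(4, 5)),
                         "AF-1", "REC1-REC1"),
    `CP-2` = place_dimer(rec, rec, dimer_pose_spec(c(1, 2)),
                         "CP-2", "REC1-REC1"),
    `CP-3` = place_dimer(rec, rec, dimer_pose_spec(c(6, 7)),
                         "CP-3", "REC1-REC1"),
    `CP-4` = make_decoy(place_dimer(rec, rec, dimer_pose_spec(c(4, 5)),
                                    "CP-4", "REC1-REC1"), "flip"))
  het <- list(
    `AF-1` = place_dimer(rec, iso, dimer_pose_spec(c(4, 5), c(1, 2)),
                         "AF-1", "REC1-Iso_2TM"),
    `CP-2` = place_dimer(rec, iso, dimer_pose_spec(c(6, 7), c(1, 2)),
                         "CP-2", "REC1-Iso_2TM"),
    `CP-3` = make_decoy(place_dimer(rec, iso,
                                    dimer_pose_spec(c(1, 2), c(1, 2)),
                                    "CP-3", "REC1-Iso_2TM"), "offset"))
  paths1 <- vapply(names(homo), function(lab) {
    write_model(homo[[lab]], paste0("homo_", gsub("-", "", lab), ".pdb"))
  }, character(1))
  paths2 <- vapply(names(het), function(lab) {
    write_model(het[[lab]], paste0("het_", gsub("-", "", lab), ".pdb"))
  }, character(1))

  bfe1 <- data.frame(label = names(homo), mean = c(-80, -78, -60, -90),
                     sem = c(0.2, 0.3, 0.2, 0.4))
  bfe2 <- data.frame(label = names(het), mean = c(-104, -95, -99),
                     sem = c(0.3, 0.2, 0.3))
  utils::write.table(bfe1, file.path(dir, "bfe_homo.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(bfe2, file.path(dir, "bfe_het.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  et <- synth_energy_table(homo[["AF-1"]], total_bfe_mean = -80,
                           seed = seed)
  write_energy_table(et, file.path(dir, "energy_homo_AF1.csv"))

  config <- list(
    groups = list(
      list(name = "REC1-REC1",
           models = data.frame(label = names(homo), path = unname(paths1),
                               stringsAsFactors = FALSE),
           bfe = bfe1,
           energy = list(`AF-1` = file.path(dir, "energy_homo_AF1.csv"))),
      list(name = "REC1-Iso_2TM",
           models = data.frame(label = names(het), path = unname(paths2),
                               stringsAsFactors = FALSE),
           bfe = bfe2)),
    blocking = data.frame(
      dimer_group = "REC1-REC1", dimer_label = "AF-1",
      blocker_group = "REC1-Iso_2TM", blocker_label = "AF-1",
      stringsAsFactors = FALSE),
    seed = seed)
  jsonlite::write_json(config, file.path(dir, "screen_config.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  config
}
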