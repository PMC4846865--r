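# Configuration-driven orchestration: a synthetic two-receptor demo dataset
# and a staged pipeline writing CSV tables plus a JSON manifest.

#' CDR loop sequence table
#'
#' The six complementarity-determining-region loop sequences of the A6 and
#' DMF5 T cell receptors (alpha chains share the same germline CDR1/CDR2).
#'
#' @param receptor \code{"A6"} or \code{"DMF5"}.
#' @return Data frame with columns \code{name}, \code{chain} (A = alpha,
#'   B = beta) and \code{sequence}.
#' @export
cdr_loop_table <- function(receptor = c("A6", "DMF5")) {
  receptor <- match.arg(receptor)
  seqs <- switch(receptor,
    A6 = c(CDR1a = "DRGSQS", CDR2a = "IYSNGD", CDR3a = "AVTTDSWGKLQ",
           CDR1b = "MNHEY", CDR2b = "SVGAGI", CDR3b = "ASRPGLAGGRPEQY"),
    DMF5 = c(CDR1a = "DRGSQS", CDR2a = "IYSNGD", CDR3a = "AVNFGGGKLI",
             CDR1b = "MRHNA", CDR2b = "SNTAGT", CDR3b = "ASSLSFGTEAF"))
  data.frame(name = names(seqs),
             chain = c("A", "A", "A", "B", "B", "B"),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

# concatenate structure models (atom tables and first-frame coordinates)
combine_models <- function(models) {
  structure_model(do.call(rbind, lapply(models, function(m) m$atoms)),
                  unlist(lapply(models, function(m) m$xyz)))
}

# translate all atoms of a structure model
translate_model <- function(model, shift) {
  model$xyz <- model$xyz + rep(shift, length.out = length(model$xyz))
  model
}

#' Generate the synthetic demo dataset
#'
#' Builds, for each receptor, a two-chain toy topology whose chains embed the
#' receptor's six CDR loop sequences between short linkers, and a Gaussian
#' ensemble realizing a planted dynamic contrast: the hypervariable CDR3
#' loops get receptor-specific fluctuation amplitudes (large and uncorrelated
#' for the A6-like toy; small, with correlated CDR3a/CDR3b motion, for the
#' DMF5-like toy) against a quiet baseline. Crystal-model B-factors are set
#' consistently with the planted amplitudes. Everything is written through
#' the public multi-model PDB interface so a pipeline run exercises file I/O
#' end to end.
#'
#' @param dir Output directory (created if needed).
#' @param seed Global seed; per-receptor substreams are derived from it.
#' @param n_frames Frames per ensemble (default 300).
#' @return Invisibly, a list with the written file paths and the planted
#'   per-loop sigma table.
#' @export
generate_demo_data <- function(dir, seed, n_frames = 300) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(dir = dir, receptors = list())
  for (rec in c("A6", "DMF5")) {
    cdr <- cdr_loop_table(rec)
    mk_chain <- function(ch) {
      loops <- cdr[cdr$chain == ch, ]
      paste0("TS", loops$sequence[1], "TS", loops$sequence[2], "TS",
             loops$sequence[3], "TS")
    }
    chainA <- build_peptide(mk_chain("A"), chain = "A")
    chainB <- translate_model(build_peptide(mk_chain("B"), chain = "B"),
                              c(0, 4.8, 0))
    topo <- combine_models(list(chainA, chainB))
    loops <- resolve_loops(topo, cdr)

    reskey <- unique(paste(topo$atoms$chain, topo$atoms$resno, sep = "|"))
    n_res <- length(reskey)
    sigma <- rep(0.25, n_res)
    rho <- diag(1, n_res)
    idx_of <- function(lp) match(paste(lp$chain, lp$resno, sep = "|"), reskey)
    i3a <- idx_of(loops[[3]]); i3b <- idx_of(loops[[6]])
    if (rec == "A6") {
      # mobile, mutually uncorrelated hypervariable loops
      sigma[i3a] <- 1.7
      sigma[i3b] <- 2.9
      rho[i3a, i3a] <- 0.3; rho[i3b, i3b] <- 0.3
    } else {
      # quieter hypervariable loops with planted CDR3a/CDR3b coupling
      sigma[i3a] <- 1.15
      sigma[i3b] <- 0.58
      rho[i3a, i3a] <- 0.6; rho[i3b, i3b] <- 0.6
      rho[i3a, i3b] <- 0.42; rho[i3b, i3a] <- 0.42
    }
    diag(rho) <- 1

    b_res <- (8 * pi^2 / 3) * (3 * sigma^2)   # B from planted RMSF sigma*sqrt(3)
    atom_key <- paste(topo$atoms$chain, topo$atoms$resno, sep = "|")
    topo$atoms$b <- b_res[match(atom_key, reskey)]

    ens <- gaussian_ensemble(topo, sigma, rho, n_frames,
                             seed = substream_seed(seed, rec))
    ens_path <- file.path(dir, paste0(tolower(rec), "_ensemble.pdb"))
    cry_path <- file.path(dir, paste0(tolower(rec), "_crystal.pdb"))
    write_ensemble(ens, ens_path)
    write_ensemble(ensemble(topo, matrix(topo$xyz, nrow = 1)), cry_path)
    loops_path <- file.path(dir, paste0(tolower(rec), "_loops.csv"))
    write.csv(cdr, loops_path, row.names = FALSE)
    out$receptors[[rec]] <- list(ensemble = ens_path, crystal = cry_path,
                                 loops = loops_path,
                                 sigma = data.frame(residue = reskey,
                                                    sigma = sigma))
  }
  cfg <- list(
    seed = seed,
    outdir = file.path(dir, "results"),
    stages = c("rmsf", "orderparams", "dccm", "lmi", "communities",
               "phipsi", "hbonds", "sasa", "regress"),
    ensembles = lapply(out$receptors, function(x) x$ensemble),
    crystals = lapply(out$receptors, function(x) x$crystal),
    loops = lapply(out$receptors, function(x) x$loops),
    parameters = list(lmi_min = 0.4, dist_range = c(8, 10), dist_step = 0.5,
                      occupancy_floor = 10, probe_radius = 1.4,
                      points_per_atom = 240, n_excluded = 5,
                      hbond_groupA_chain = "A", hbond_groupB_chain = "B"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  out$config <- cfg_path
  invisible(out)
}

.known_stages <- c("rmsf", "orderparams", "dccm", "lmi", "communities",
                   "phipsi", "hbonds", "sasa", "regress")

#' Run the staged analysis pipeline
#'
#' Validates the configuration, reads each ensemble, superposes it on its
#' alpha carbons, executes the requested stages in dependency order and
#' writes one CSV per stage and dataset plus a JSON manifest recording
#' parameters, package version, seed and per-stage status. Any stage error
#' aborts the run with the failing stage named; outputs written so far are
#' retained and the manifest carries a FAILED marker.
#'
#' @param config A list, or path to a YAML file, with fields
#'   \code{ensembles} (named paths), optional \code{crystals} and \code{loops}
#'   (named paths, aligned with \code{ensembles}), \code{stages},
#'   \code{outdir}, \code{seed} and \code{parameters}.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stages <- config$stages
  bad <- setdiff(stages, .known_stages)
  if (length(bad) > 0) {
    stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "))
  }
  for (p in unlist(c(config$ensembles, config$crystals, config$loops))) {
    if (!file.exists(p)) stop("configured input does not exist: ", p)
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prm <- config$parameters
  gp <- function(name, default) if (!is.null(prm[[name]])) prm[[name]] else default

  manifest <- list(package = "loopdyn",
                   version = as.character(utils::packageVersion("loopdyn")),
                   seed = config$seed, parameters = prm,
                   conventions = list(
                     angle_wrap = "(-180, 180]",
                     lmi_log_base = "natural (nats)",
                     occupancy_floor = gp("occupancy_floor", 10),
                     n_excluded = gp("n_excluded", 5),
                     rmsf_reference = "ensemble mean"),
                   stages = list(), status = "RUNNING")
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  on.exit(save_manifest())

  run_stage <- function(stage, dataset, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status <<- paste0("FAILED at stage '", stage, "' (", dataset,
                                 ")")
      manifest$stages[[paste(stage, dataset, sep = ":")]] <<-
        list(status = "FAILED", error = conditionMessage(res))
      save_manifest()
      stop("pipeline stage '", stage, "' failed on dataset '", dataset,
           "': ", conditionMessage(res))
    }
    manifest$stages[[paste(stage, dataset, sep = ":")]] <<-
      list(status = "OK", outputs = res)
    res
  }

  for (nm in names(config$ensembles)) {
    ens <- read_ensemble(config$ensembles[[nm]])
    ca <- selection_mask(ens, elety = "CA")
    ens <- superpose(ens, ca, reference = 1L)
    crystal <- if (!is.null(config$crystals[[nm]])) {
      read_structure(config$crystals[[nm]])
    } else NULL
    loops <- if (!is.null(config$loops[[nm]])) {
      resolve_loops(ens$topology, read.csv(config$loops[[nm]],
                                           stringsAsFactors = FALSE))
    } else NULL
    path_of <- function(tag) file.path(outdir, paste0(tag, "_", nm, ".csv"))

    prof <- NULL
    if ("rmsf" %in% stages || "regress" %in% stages) {
      prof <- bfactor_from_rmsf(rmsf(ens, ca))
    }
    if ("rmsf" %in% stages) {
      run_stage("rmsf", nm, function() {
        write.csv(prof, path_of("rmsf"), row.names = FALSE)
        path_of("rmsf")
      })
    }
    if ("orderparams" %in% stages) {
      run_stage("orderparams", nm, function() {
        vt <- extract_vectors(ens)
        ops <- ired_order_parameters(vt, n_excluded = gp("n_excluded", 5))
        write.csv(ops$profile, path_of("orderparams"), row.names = FALSE)
        path_of("orderparams")
      })
    }
    cm <- NULL
    if ("dccm" %in% stages) {
      run_stage("dccm", nm, function() {
        cm <<- dccm(ens, ca)
        write.csv(cm$matrix, path_of("dccm"), row.names = TRUE)
        paths <- path_of("dccm")
        if (!is.null(loops)) {
          lpa <- loop_pair_average(cm, loops)
          write.csv(lpa, path_of("loop_correlation"), row.names = TRUE)
          paths <- c(paths, path_of("loop_correlation"))
        }
        paths
      })
    }
    lm_cm <- NULL
    if ("lmi" %in% stages || "communities" %in% stages) {
      run_stage("lmi", nm, function() {
        lm_cm <<- lmi(ens, ca)
        write.csv(lm_cm$matrix, path_of("lmi"), row.names = TRUE)
        path_of("lmi")
      })
    }
    if ("communities" %in% stages) {
      run_stage("communities", nm, function() {
        net <- build_network(lm_cm, lmi_min = gp("lmi_min", 0.4),
                             dist_range = unlist(gp("dist_range", c(8, 10))),
                             step = gp("dist_step", 0.5))
        part <- net$partition
        df <- data.frame(residue = names(part$membership),
                         community = as.integer(part$membership))
        df$selected_cutoff <- net$cutoff
        write.csv(df, path_of("communities"), row.names = FALSE)
        el <- igraph::as_edgelist(net$graph)
        utils::write.table(el, path_of("network_edges"), sep = ",",
                           row.names = FALSE,
                           col.names = c("from", "to"))
        c(path_of("communities"), path_of("network_edges"))
      })
    }
    if ("phipsi" %in% stages) {
      run_stage("phipsi", nm, function() {
        tgt <- gp("phipsi_residue", NULL)
        if (is.null(tgt)) {
          # default: apex residue of the last resolved loop
          lp <- loops[[length(loops)]]
          tgt <- list(chain = lp$chain,
                      resno = lp$resno[ceiling(length(lp$resno) / 2)])
        }
        ser <- phi_psi(ens, tgt)
        ref <- gp("phipsi_ref", NULL)
        if (is.null(ref)) {
          cry_ens <- ensemble(ens$topology,
                              matrix(if (is.null(crystal)) ens$xyz[1, ]
                                     else crystal$xyz, nrow = 1))
          cser <- phi_psi(cry_ens, tgt)
          ref <- c(cser$phi[1], cser$psi[1])
        }
        occ <- box_occupancy(ser, ref, halfwidth = gp("box_halfwidth", 30))
        ser$residue <- paste0(tgt$chain, tgt$resno)
        write.csv(ser, path_of("phipsi"), row.names = FALSE)
        write.csv(data.frame(residue = paste0(tgt$chain, tgt$resno),
                             phi0 = ref[1], psi0 = ref[2],
                             halfwidth = occ$halfwidth,
                             percent = occ$percent),
                  path_of("box_occupancy"), row.names = FALSE)
        c(path_of("phipsi"), path_of("box_occupancy"))
      })
    }
    if ("hbonds" %in% stages) {
      run_stage("hbonds", nm, function() {
        om <- occupancy_map(ens,
                            groupA = list(chain = gp("hbond_groupA_chain", "A")),
                            groupB = list(chain = gp("hbond_groupB_chain", "B")),
                            crystal = crystal,
                            occupancy_floor = gp("occupancy_floor", 10))
        write.csv(as.data.frame(om), path_of("hbonds"), row.names = FALSE)
        path_of("hbonds")
      })
    }
    sp <- NULL
    if ("sasa" %in% stages || "regress" %in% stages) {
      run_stage("sasa", nm, function() {
        target <- if (is.null(crystal)) ens$topology else crystal
        sp <<- relative_sasa(sasa(target,
                                  probe_radius = gp("probe_radius", 1.4),
                                  points_per_atom = gp("points_per_atom", 240)))
        write.csv(sp, path_of("sasa"), row.names = FALSE)
        path_of("sasa")
      })
    }
    if ("regress" %in% stages) {
      run_stage("regress", nm, function() {
        src <- if (is.null(crystal)) ens$topology else crystal
        b_ca <- src$atoms$b[src$atoms$elety == "CA"]
        key_prof <- paste(prof$chain, prof$resno)
        key_sasa <- paste(sp$chain, sp$resno)
        m <- match(key_prof, key_sasa)
        model <- fit_rmsf_model(prof$rmsf, b_ca, sp$relative[m])
        write.csv(data.frame(coefficient = c("a_relative_sasa", "b_bfactor",
                                             "c_intercept", "pearson_r"),
                             value = c(model$a, model$b, model$c, model$r),
                             unit = c(model$units, "dimensionless")),
                  path_of("regression"), row.names = FALSE)
        path_of("regression")
      })
    }
  }
  manifest$status <- "OK"
  save_manifest()
  invisible(manifest)
}
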