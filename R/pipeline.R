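#' Run the simulate -> genotype -> infer -> analyze -> cooccur pipeline
#'
#' Executes the requested stages in order against a single output
#' directory, records a manifest (seeds, parameters, file hashes, per-stage
#' runtimes), and on re-runs skips stages whose parameters and upstream
#' input hashes are unchanged. Identical configuration and seeds give
#' byte-identical outputs.
#'
#' @param config A configuration list or path to a YAML file with fields:
#'   `out_dir`, `seed`, `stages` (subset of `simulate`, `genotype`,
#'   `infer`, `analyze`, `cooccur`), and optional per-stage parameter lists
#'   `simulate`, `genotype`, `infer`, `analyze` (see
#'   [simulate_sample()], [call_genotype()], [mcmc_infer()],
#'   [compose_clones()]).
#' @return The run manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE) else NULL
  manifest <- list(package_version = as.character(utils::packageVersion("clonalevo")),
                   seed = config$seed, config = config, stages = list())

  paths <- list(
    truth = file.path(out, "truth.json"),
    gt = file.path(out, "sample.gt.tsv"),
    depth = file.path(out, "depth.tsv"),
    alt = file.path(out, "alt.tsv"),
    called = file.path(out, "called.gt.tsv"),
    qc = file.path(out, "sample.qc.json"),
    tree = file.path(out, "map_tree.json"),
    newick = file.path(out, "map_tree.nwk"),
    posterior = file.path(out, "posterior_summary.json"),
    attach = file.path(out, "attachment.tsv"),
    composition = file.path(out, "composition.tsv"),
    prevalence = file.path(out, "prevalence.tsv"),
    evolution = file.path(out, "evolution.json"),
    cooccur = file.path(out, "cooccurrence.tsv"))

  stage_unchanged <- function(name, inputs, outputs) {
    if (is.null(old_manifest)) return(FALSE)
    rec <- old_manifest$stages[[name]]
    if (is.null(rec)) return(FALSE)
    if (!identical(jsonlite::toJSON(config[[name]], auto_unbox = TRUE),
                   jsonlite::toJSON(old_manifest$config[[name]],
                                    auto_unbox = TRUE))) return(FALSE)
    if (!all(file.exists(outputs))) return(FALSE)
    hashes <- unname(tools::md5sum(inputs[file.exists(inputs)]))
    identical(as.character(hashes), as.character(unlist(rec$input_md5)))
  }
  record_stage <- function(name, inputs, outputs, runtime, cached = FALSE) {
    manifest$stages[[name]] <<- list(
      cached = cached,
      input_md5 = as.list(unname(tools::md5sum(inputs[file.exists(inputs)]))),
      output_md5 = as.list(unname(tools::md5sum(outputs[file.exists(outputs)]))),
      runtime_s = round(runtime, 3))
  }
  write_tsv_matrix <- function(m, path) {
    utils::write.table(data.frame(cell_id = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("simulate" %in% config$stages) {
    ins <- character(0)
    outs <- c(paths$truth, paths$gt, paths$depth, paths$alt)
    if (stage_unchanged("simulate", ins, outs)) {
      record_stage("simulate", ins, outs, 0, cached = TRUE)
    } else {
      t0 <- proc.time()[3L]
      sim <- do.call(simulate_sample,
                     c(config$simulate, list(seed = config$seed)))
      write_simulation_truth(sim$truth, paths$truth)
      write_genotype_tsv(do.call(rbind, sim$genotypes), paths$gt)
      write_tsv_matrix(do.call(rbind, lapply(sim$reads, `[[`, "depth")),
                       paths$depth)
      write_tsv_matrix(do.call(rbind, lapply(sim$reads, `[[`, "alt")),
                       paths$alt)
      record_stage("simulate", ins, outs, proc.time()[3L] - t0)
    }
  }

  if ("genotype" %in% config$stages) {
    ins <- c(paths$depth, paths$alt)
    outs <- c(paths$called, paths$qc)
    if (stage_unchanged("genotype", ins, outs)) {
      record_stage("genotype", ins, outs, 0, cached = TRUE)
    } else {
      t0 <- proc.time()[3L]
      if (!all(file.exists(ins))) stop("genotype stage: missing read counts")
      reads <- list(depth = read_count_tsv(paths$depth),
                    alt = read_count_tsv(paths$alt))
      called <- do.call(call_genotype_matrix,
                        c(list(reads = reads), config$genotype,
                          list(zygosity = TRUE)))
      snp <- grep("^snp", colnames(called), value = TRUE)
      qc <- sample_qc(called, reads, snp_loci = snp)
      jsonlite::write_json(qc, paths$qc, auto_unbox = TRUE, digits = NA)
      write_genotype_tsv(called, paths$called)
      record_stage("genotype", ins, outs, proc.time()[3L] - t0)
    }
  }

  if ("infer" %in% config$stages) {
    ins <- paths$gt
    outs <- c(paths$tree, paths$newick, paths$posterior, paths$attach)
    if (stage_unchanged("infer", ins, outs)) {
      record_stage("infer", ins, outs, 0, cached = TRUE)
    } else {
      t0 <- proc.time()[3L]
      if (!file.exists(paths$gt)) stop("infer stage: missing genotype matrix")
      gt <- read_genotype_tsv(paths$gt)
      pars <- config$infer
      errors <- error_model(fpr = pars$fpr %||% 0.01,
                            fnr = pars$ado %||% 0.058)
      cfg <- mcmc_config(chain_length = pars$chain_length %||% 20000,
                         n_chains = pars$n_chains %||% 2L,
                         seed = config$seed,
                         model_id = pars$model_id %||% 2L)
      fit <- mcmc_infer(gt, errors, cfg)
      att <- attach_cells(fit)
      tree_to_json(fit$map_tree, paths$tree)
      writeLines(tree_to_newick(fit$map_tree), paths$newick)
      jsonlite::write_json(list(map_loglik = fit$map_loglik,
                                rhat = fit$rhat,
                                accept_tree = fit$accept_tree,
                                mean_fnr = colMeans(fit$beta)),
                           paths$posterior, auto_unbox = TRUE, digits = NA)
      write_attachment_tsv(att, paths$attach)
      saveRDS(att, file.path(out, "scratch_attachment.rds"))
      record_stage("infer", ins, outs, proc.time()[3L] - t0)
    }
  }

  if ("analyze" %in% config$stages) {
    ins <- paths$attach
    outs <- c(paths$composition, paths$prevalence, paths$evolution)
    if (stage_unchanged("analyze", ins, outs)) {
      record_stage("analyze", ins, outs, 0, cached = TRUE)
    } else {
      t0 <- proc.time()[3L]
      att_file <- file.path(out, "scratch_attachment.rds")
      if (!file.exists(att_file)) stop("analyze stage: run infer first")
      att <- readRDS(att_file)
      comp <- compose_clones(att,
                             threshold = config$analyze$threshold %||% 0.01)
      write_composition_tsv(comp, paths$composition, paths$prevalence)
      call <- classify_evolution(att$tree, comp)
      jsonlite::write_json(list(pattern = call$pattern,
                                convergent = call$convergent,
                                shannon_bits = shannon_index(comp)),
                           paths$evolution, auto_unbox = TRUE, digits = NA)
      record_stage("analyze", ins, outs, proc.time()[3L] - t0)
    }
  }

  if ("cooccur" %in% config$stages) {
    ins <- paths$gt
    outs <- paths$cooccur
    if (stage_unchanged("cooccur", ins, outs)) {
      record_stage("cooccur", ins, outs, 0, cached = TRUE)
    } else {
      t0 <- proc.time()[3L]
      gt <- read_genotype_tsv(paths$gt)
      res <- cell_cooccurrence(gt)
      write_cooccurrence_tsv(res, paths$cooccur)
      record_stage("cooccur", ins, outs, proc.time()[3L] - t0)
    }
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_count_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

validate_run_config <- function(config) {
  if (is.null(config$out_dir)) stop("config field out_dir is required")
  if (is.null(config$seed)) stop("config field seed is required (no silent entropy)")
  config$seed <- as.integer(config$seed)
  all_stages <- c("simulate", "genotype", "infer", "analyze", "cooccur")
  if (is.null(config$stages)) config$stages <- all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (!is.null(config$infer$model_id) && !config$infer$model_id %in% 1:4)
    stop("config field infer$model_id must be one of 1, 2, 3, 4")
  config
}

#' Summarize a completed pipeline run
#'
#' Writes a human-readable markdown report (tree, clonal composition,
#' diversity, evolution call, association table) whose numbers are read
#' back from the stage outputs; regeneration is idempotent.
#'
#' @param run_dir Output directory of [run_pipeline()].
#' @param path Report path (default `report.md` inside `run_dir`).
#' @return The report path, invisibly.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("incomplete run: no manifest found")
  lines <- c("# Clonal evolution run report", "")
  nwk <- file.path(run_dir, "map_tree.nwk")
  if (file.exists(nwk))
    lines <- c(lines, "## MAP mutation tree", "", "```",
               readLines(nwk), "```", "")
  comp <- file.path(run_dir, "composition.tsv")
  if (file.exists(comp)) {
    df <- utils::read.delim(comp)
    lines <- c(lines, "## Clonal composition", "",
               paste0(nrow(df), " subclones"),
               paste0("- ", df$clone, " {", df$mutations, "}: ",
                      df$n_cells, " cells (",
                      round(100 * df$fraction, 1), "%)"), "")
  }
  evo <- file.path(run_dir, "evolution.json")
  if (file.exists(evo)) {
    e <- jsonlite::fromJSON(evo)
    lines <- c(lines, "## Evolution",
               paste0("- pattern: ", e$pattern,
                      if (isTRUE(e$convergent)) " (convergent)" else ""),
               paste0("- Shannon index: ", round(e$shannon_bits, 3),
                      " bits"), "")
  }
  coo <- file.path(run_dir, "cooccurrence.tsv")
  lines <- c(lines, "## Association")
  if (file.exists(coo)) {
    df <- utils::read.delim(coo)
    sig <- df[!is.na(df$q) & df$q < 0.1, , drop = FALSE]
    lines <- c(lines, paste0(nrow(df), " pairs tested; ", nrow(sig),
                             " with q < 0.1"))
  } else {
    lines <- c(lines, "not run")
  }
  writeLines(lines, path)
  invisible(path)
}
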