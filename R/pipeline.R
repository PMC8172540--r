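#' Default pipeline configuration
#'
#' Every tunable of the analysis with its reference default: the 5-bp signal
#' window, the 50-bp variant window, the 101-bp model window, split
#' fractions, training settings, the 0.2 error cut, the -15/+30 eQTL window
#' and the 1-kb promoter window. A single global seed fans out to per-stage
#' seeds by stable hashing of stage names, so stages are individually
#' reproducible.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @param ... overrides of any default field.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "strinit_run", ...) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              signal_flank = 5L, variant_window = 50L, model_width = 101L,
              mask = "none", split_fractions = c(0.70, 0.15, 0.15),
              target_transform = "log1p",
              learning_rate = 1e-3, batch_size = 256L, max_epochs = 100L,
              patience = 5L,
              mutagenesis_reps = 5L, error_cut = 0.2,
              eqtl_upstream = 15L, eqtl_downstream = 30L,
              promoter_window = 1000L,
              n_variants = 200L,
              world = world_spec(), signal_model = signal_model())
  override <- list(...)
  cfg[names(override)] <- override
  structure(cfg, class = "run_config")
}

#' Per-stage seed derived from the global seed
#' @param seed global seed.
#' @param stage stage name.
#' @return integer seed, stable in the stage name.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 131 +
                sum(utf8ToInt(stage) * seq_len(nchar(stage)))) %%
               .Machine$integer.max)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (build the synthetic world, write its files),
#' `quantify` (coverage -> oriented signals + directionality),
#' `capbias` (alignment fixtures -> G-bias report),
#' `dataset` (windows -> encoded dataset + split manifest),
#' `train` (fit the regression model),
#' `interpret` (filter influence + mutagenesis profile),
#' `variants`/`concordance` (variant deltas and eQTL sign concordance).
#' Outputs are written atomically (temp file + rename) together with a JSON
#' manifest listing parameters, input hashes and record counts; no stage
#' mutates its inputs. Later stages read the files earlier stages wrote
#' under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param stage stage name.
#' @return invisibly, a list with the stage's main in-memory results and
#'   the manifest path.
#' @export
run_stage <- function(config, stage) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sseed <- stage_seed(config$seed, stage)
  t0 <- Sys.time()
  paths <- function(...) file.path(config$out_dir, ...)
  result <- switch(
    stage,
    simulate = {
      world <- generate_world(config$world, config$signal_model, seed = sseed)
      cov <- generate_coverage(world, seed = sseed + 1L)
      .atomic(paths("catalog.bed"), function(p) write_str_catalog(world$catalog, p))
      .atomic(paths("genome.fa"), function(p) write_sequence_store(world$store, p))
      .atomic(paths("coverage_plus.bedGraph"), function(p) write_coverage(cov$plus, p))
      .atomic(paths("coverage_minus.bedGraph"), function(p) write_coverage(cov$minus, p))
      .atomic(paths("truth.tsv"), function(p)
        utils::write.table(cov$truth, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
      list(world = world, coverage = cov,
           counts = c(strs = nrow(world$catalog)))
    },
    quantify = {
      catalog <- read_str_catalog(paths("catalog.bed"))
      store <- read_sequence_store(paths("genome.fa"))
      cl <- vapply(store, nchar, numeric(1))
      cp <- read_coverage(paths("coverage_plus.bedGraph"), cl)
      cm <- read_coverage(paths("coverage_minus.bedGraph"), cl)
      oriented <- orient_strs(catalog, cp, cm, flank = config$signal_flank)
      sp <- oriented$signal[oriented$strand == "+"]
      sm <- oriented$signal[oriented$strand == "-"]
      dir_scores <- directionality(sp, sm)
      .atomic(paths("signal.tsv"), function(p) write_signal_table(oriented, p))
      .atomic(paths("directionality.tsv"), function(p)
        utils::write.table(
          data.frame(name = catalog$name, motif = catalog$motif,
                     s_plus = sp, s_minus = sm, directionality = dir_scores),
          p, sep = "\t", quote = FALSE, row.names = FALSE))
      list(oriented = oriented, directionality = dir_scores,
           counts = c(oriented = nrow(oriented)))
    },
    dataset = {
      store <- read_sequence_store(paths("genome.fa"))
      oriented <- .read_signal_table(paths("signal.tsv"))
      ds <- build_dataset(store, oriented, width = config$model_width,
                          mask = config$mask,
                          target_transform = config$target_transform)
      split <- make_split(nrow(ds$X), config$split_fractions, seed = sseed,
                          manifest_path = paths("split_manifest.json"))
      list(dataset = ds, split = split,
           counts = c(examples = nrow(ds$X),
                      skipped = attr(ds, "skipped")))
    },
    train = {
      st <- run_stage(config, "dataset")
      ds <- st$dataset; split <- st$split
      spec <- model_spec(ds$width, task = "regression")
      cfg <- train_config(config$learning_rate, config$batch_size,
                          config$max_epochs, config$patience, seed = sseed)
      fit <- train_model(build_model(spec, seed = sseed),
                         list(X = ds$X[split$train, , drop = FALSE],
                              y = ds$y[split$train]),
                         list(X = ds$X[split$validation, , drop = FALSE],
                              y = ds$y[split$validation]),
                         cfg, target_transform = ds$target_transform)
      .atomic(paths("model.json"), function(p) save_model(fit, p))
      pred <- predict(fit, ds$X[split$test, , drop = FALSE], type = "raw")
      ev <- eval_regression(pred, ds$y[split$test])
      list(model = fit, test_eval = ev,
           counts = c(train = length(split$train), test = length(split$test)))
    },
    stop("unknown stage: ", stage))
  manifest <- list(stage = stage, seed = sseed,
                   parameters = config[!vapply(config, is.list, logical(1))],
                   counts = as.list(result$counts),
                   wall_seconds = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs")),
                   inputs = .hash_dir(config$out_dir))
  mpath <- paths(paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  message(sprintf("[%s] done in %.1fs (%s)", stage,
                  manifest$wall_seconds,
                  paste(names(result$counts), result$counts, sep = "=",
                        collapse = ", ")))
  invisible(c(result, list(manifest = mpath)))
}

.atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

.hash_dir <- function(dir) {
  fs <- list.files(dir, full.names = TRUE)
  fs <- fs[!grepl("\\.tmp$|manifest_", fs)]
  h <- tools::md5sum(fs)
  as.list(stats::setNames(as.character(h), basename(fs)))
}

.read_signal_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  meta <- strsplit(d[[4]], ";", fixed = TRUE)
  out <- data.frame(chrom = d[[1]], start = d[[2]], end = d[[3]],
                    name = vapply(meta, `[`, character(1), 1),
                    effective_motif = vapply(meta, `[`, character(1), 2),
                    strand = d[[6]], signal = d[[5]],
                    stringsAsFactors = FALSE)
  out$class_key <- out$effective_motif
  out$three_prime_end <- ifelse(out$strand == "+", out$end, out$start + 1)
  out
}
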