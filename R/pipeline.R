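#' Default pipeline configuration
#'
#' One nested list holding every stage's parameters plus the global seed.
#' `simulate$enabled = TRUE` runs the synthetic generator; otherwise
#' `input$text` / `input$metadata` are read. Any subset of the defaults can
#' be overridden through `overrides` (recursively merged), or loaded from a
#' YAML file with [read_pipeline_config()]. The effective configuration is
#' written to the output directory on every run so results are reproducible
#' from the artifact alone.
#'
#' @param overrides Nested list merged over the defaults.
#' @return A `datm_config` list.
#' @export
datm_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    simulate = list(enabled = TRUE, V = 500, N = 30, K_true = 10, s_true = 1,
                    alpha = 0.1, beta = 0.2, drift = 0.05, docs = 300,
                    doc_len = 80, axis_gap = 1.5, group_effect = 2,
                    noise_sd = 0.05, word_scale = 5, zipf_exponent = 1.0,
                    n_anchor_pairs = 8),
    input = list(text = NULL, metadata = NULL),
    preprocess = list(min_count = 5, phrase_delta = 5, phrase_threshold = 10,
                      phrase_passes = 2),
    embedding = list(dim = 30, window = 5),
    atoms = list(K = 10, s = 2, iters = 15),
    sif = list(a = 1e-3, window_size = 10, stride = 5),
    dimension = list(pairs = NULL, name = "planted-axis"),
    associate = list(group_var = "group", top_n = 7)
  )
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "datm_config")
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' YAML 1.1 resolves a bare `N` key to boolean FALSE; since `N` (embedding
#' dimension of the simulator) is the only field name with that problem, a
#' key parsed as `FALSE` is renamed back to `N`. Quoting (`'N': 50`) works
#' too.
#'
#' @param path YAML file with any subset of the [datm_config()] fields.
#' @export
read_pipeline_config <- function(path) {
  fix_n <- function(x) {
    if (!is.list(x)) return(x)
    names(x)[names(x) %in% c("FALSE", "no")] <- "N"
    lapply(x, fix_n)
  }
  datm_config(fix_n(yaml::read_yaml(path)))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

# All pipeline TSVs carry a sidecar-style header with the config hash and
# seed, so every artifact is traceable to its run.
write_stage_tsv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# datm config_hash=%s seed=%d", hash, seed), con)
  close(con)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE)
  )
  invisible(path)
}

#' Run the full discourse-atom pipeline
#'
#' Chains simulate (or load) -> preprocess (phrase merge, vocabulary) ->
#' embed -> fit-atoms -> assign -> dimension -> associate, writing every
#' stage's artifact as TSV/text into `out_dir` together with the effective
#' YAML config. When the corpus is simulated, a recovery report (optimal
#' label matching and window accuracy against the planted truth) is written
#' too. Fully deterministic given (config, seed).
#'
#' @param config A [datm_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory objects of every stage
#'   (corpus, vocab, embedding, dict, topics, dimension, prevalence,
#'   correlation, recovery, paths).
#' @export
run_pipeline <- function(config = datm_config(), out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- as.integer(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))

  sim <- NULL
  if (isTRUE(config$simulate$enabled)) {
    say("stage simulate: generating synthetic corpus")
    scfg <- do.call(sim_config, c(config$simulate[setdiff(names(config$simulate),
                                                          "enabled")],
                                  list(seed = seed)))
    space <- plant_space(scfg)
    sim <- generate_corpus(scfg, space)
    corpus_raw <- sim$corpus
    write_corpus(corpus_raw, file.path(out_dir, "corpus.txt"),
                 file.path(out_dir, "metadata.tsv"))
  } else {
    if (is.null(config$input$text)) {
      stop("run_pipeline: simulate disabled and no input$text given")
    }
    say("stage preprocess: loading %s", config$input$text)
    corpus_raw <- load_corpus(config$input$text, config$input$metadata)
  }

  say("stage preprocess: phrase merge + vocabulary")
  pp <- config$preprocess
  corpus <- merge_phrases(corpus_raw, delta = pp$phrase_delta,
                          threshold = pp$phrase_threshold,
                          passes = pp$phrase_passes)
  vocab <- build_vocabulary(corpus, min_count = pp$min_count)
  write_vocabulary(vocab, file.path(out_dir, "vocabulary.tsv"))

  say("stage embed: %d terms -> %d dims", length(vocab), config$embedding$dim)
  emb <- train_embedding(corpus, vocab, dim = config$embedding$dim,
                         window = config$embedding$window)
  write_embedding(emb, file.path(out_dir, "embedding.vec"))

  say("stage fit-atoms: K-SVD with K=%d s=%d", config$atoms$K, config$atoms$s)
  X <- unit_rows(emb$vectors)
  dict <- ksvd_fit(X, K = config$atoms$K, s = config$atoms$s,
                   iters = config$atoms$iters, seed = seed)
  write_dictionary(dict, file.path(out_dir, "atoms.vec"),
                   file.path(out_dir, "codes.tsv"))
  write_stage_tsv(topics_table(dict, emb, n = config$associate$top_n),
                  file.path(out_dir, "topics.tsv"), hash, seed)
  write_stage_tsv(score_model(dict, emb,
                              top_n = min(10, length(vocab))),
                  file.path(out_dir, "model_score.tsv"), hash, seed)

  say("stage assign: rolling windows -> topics")
  scfg_sif <- sif_config(a = config$sif$a,
                         window_size = config$sif$window_size,
                         stride = config$sif$stride)
  topics <- corpus_topics(corpus, emb, dict, scfg_sif, seed = seed)
  write_topic_records(topics, file.path(out_dir, "topic_records.tsv"))

  say("stage dimension: semantic axis + loadings")
  pairs <- config$dimension$pairs
  if (is.null(pairs)) {
    pairs <- if (!is.null(sim)) sim$space$anchor_pairs else default_gender_pairs()
  }
  dimension <- build_dimension(pairs, emb, name = config$dimension$name)
  ranked <- rank_topics(dict, dimension, emb, top_n = config$associate$top_n)
  write_stage_tsv(ranked, file.path(out_dir, "loadings.tsv"), hash, seed)

  say("stage associate: prevalence + correlation")
  prev <- NULL; corr <- NULL
  gv <- config$associate$group_var
  if (gv %in% names(corpus$metadata)) {
    prev <- prevalence(topics$presence, corpus$metadata, group_var = gv)
    write_stage_tsv(prev, file.path(out_dir, "prevalence.tsv"), hash, seed)
    loadings <- ranked$loading[order(ranked$topic_id)]
    corr <- loading_prevalence_correlation(loadings, prev$ratio)
    write_stage_tsv(
      data.frame(rho = corr$rho, p = corr$p, n_used = corr$n_used,
                 n_dropped = corr$n_dropped),
      file.path(out_dir, "correlation.tsv"), hash, seed)
  }

  recovery <- NULL
  if (!is.null(sim)) {
    say("stage recovery: matched window accuracy")
    truth <- unlist(true_window_topics(sim, scfg_sif))
    assigned <- unlist(lapply(topics$records, `[[`, "sequence"))
    recovery <- window_accuracy(assigned, truth, K_fitted = dict$K,
                                K_true = sim$cfg$K_true)
    write_stage_tsv(
      data.frame(n_windows = length(truth), accuracy = recovery$accuracy,
                 matching = paste(recovery$matching, collapse = ",")),
      file.path(out_dir, "recovery.tsv"), hash, seed)
  }

  # sidecar manifest: every artifact is traceable to config hash + seed,
  # including the formats (word2vec text, raw corpus) that cannot carry a
  # comment line themselves
  arts <- sort(setdiff(list.files(out_dir), "MANIFEST.tsv"))
  write.table(data.frame(file = arts, config_hash = hash, seed = seed),
              file.path(out_dir, "MANIFEST.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(corpus = corpus, vocab = vocab, embedding = emb,
                 dict = dict, topics = topics, dimension = dimension,
                 prevalence = prev, correlation = corr, recovery = recovery,
                 sim = sim, config = config, out_dir = out_dir,
                 config_hash = hash))
}
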