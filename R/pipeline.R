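# Staged pipeline: synth -> load -> dedup -> vectorize -> select ->
# topics -> review -> trends. Each stage reads the previous stage's
# artifact from `out_dir` and writes its own, so stages can be rerun in
# isolation; a JSON manifest records parameters, seeds and artifact
# hashes. One global seed fans out to fixed per-stage offsets.

.stage_order <- c("synth", "load", "dedup", "vectorize", "select",
                  "topics", "review", "trends")
.stage_seed_offset <- c(synth = 0L, load = 0L, dedup = 0L, vectorize = 0L,
                        select = 100L, topics = 200L, review = 300L,
                        trends = 400L)

#' Pipeline configuration
#'
#' Defaults follow the method's published settings: adult cohort
#' (`min_age = 16`), n-grams up to 5 words, review parameters top 3
#' documents per topic / 7 multi-topic documents / 24 random documents at
#' the 0.03 significant-score threshold, temporal selection with top-5000
#' classifier lists, the <10% prevalence / +30% raw-frequency rules and
#' the digit-only filter.
#'
#' @param out_dir artifact directory
#' @param notes_path,codes_path input CSVs (filled in by the synth stage
#'   when it runs)
#' @param group_map_path optional admission-to-label CSV; unnecessary when
#'   the synth stage supplies ground-truth labels
#' @param target_label,comparison_label group labels contrasted by the
#'   ensemble strategy (the temporal strategy uses labels `period2`,
#'   `period3`)
#' @param synth a [synth_config()] for the synth stage
#' @param min_age cohort age filter in years
#' @param dedup_mode `"remove"` or `"mark"`
#' @param max_n,collocation_min_count,collocation_threshold vectorizer
#'   parameters (see [build_vocabulary()])
#' @param strategy `"ensemble"` or `"temporal"`
#' @param selection named list of extra arguments for the selector
#' @param K topic count for the topics stage
#' @param review named list: `top_k`, `sig_threshold`, `n_multi`, `n_random`
#' @param criteria_path named-criteria file for the trends stage
#' @param seed global integer seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(out_dir,
                            notes_path = NULL, codes_path = NULL,
                            group_map_path = NULL,
                            target_label = "target",
                            comparison_label = "comparison",
                            synth = synth_config(),
                            min_age = 16,
                            dedup_mode = "remove",
                            max_n = 5,
                            collocation_min_count = 5,
                            collocation_threshold = 10,
                            strategy = c("ensemble", "temporal"),
                            selection = list(),
                            K = 45,
                            review = list(top_k = 3, sig_threshold = 0.03,
                                          n_multi = 7, n_random = 24),
                            criteria_path = NULL,
                            seed = 1L) {
  strategy <- match.arg(strategy)
  structure(list(out_dir = out_dir, notes_path = notes_path,
                 codes_path = codes_path, group_map_path = group_map_path,
                 target_label = target_label,
                 comparison_label = comparison_label,
                 synth = synth, min_age = min_age, dedup_mode = dedup_mode,
                 max_n = max_n,
                 collocation_min_count = collocation_min_count,
                 collocation_threshold = collocation_threshold,
                 strategy = strategy, selection = selection, K = K,
                 review = review, criteria_path = criteria_path,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.artifact <- function(config, name) file.path(config$out_dir, name)

.require_artifact <- function(config, name, stage) {
  path <- .artifact(config, name)
  if (!file.exists(path)) {
    stopf("stage '%s' requires missing artifact '%s' (run its producing stage first)",
          stage, name)
  }
  path
}

.read_documents_artifact <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df$note_count <- as.integer(df$note_count)
  df$first_charttime <- as.POSIXct(df$first_charttime, tz = "UTC")
  df
}

#' Run the surveillance pipeline
#'
#' Executes the requested stages in fixed order, writing each stage's
#' artifact under `config$out_dir` and finally a JSON run manifest with
#' the seed, per-stage parameters and artifact MD5 hashes. Requesting no
#' stages writes the manifest only.
#'
#' @param config a [pipeline_config()]
#' @param stages subset of `synth`, `load`, `dedup`, `vectorize`,
#'   `select`, `topics`, `review`, `trends`
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config, stages = .stage_order) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, .stage_order)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- .stage_order[.stage_order %in% stages]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  seed_for <- function(stage) config$seed + .stage_seed_offset[[stage]]

  for (stage in stages) {
    written <- c(written, switch(stage,
      synth = {
        cfg <- config$synth
        cfg$seed <- seed_for("synth")
        paths <- write_cohort(generate_cohort(cfg), config$out_dir)
        basename(unname(paths))
      },
      load = {
        notes_path <- config$notes_path %||%
          .require_artifact(config, "notes.csv", "load")
        notes <- filter_cohort(load_notes(notes_path), config$min_age)
        groups <- if (!is.null(config$group_map_path)) {
          load_group_map(config$group_map_path)
        } else if (file.exists(.artifact(config, "ground_truth.json"))) {
          gt <- jsonlite::read_json(.artifact(config, "ground_truth.json"),
                                    simplifyVector = TRUE)
          unlist(gt$group)
        } else NULL
        docs <- assemble_documents(notes, groups = groups)
        write.csv(docs, .artifact(config, "documents.csv"), row.names = FALSE)
        "documents.csv"
      },
      dedup = {
        path <- .require_artifact(config, "documents.csv", "dedup")
        docs <- dedup_documents(.read_documents_artifact(path),
                                mode = config$dedup_mode)
        write.csv(docs, .artifact(config, "documents_dedup.csv"),
                  row.names = FALSE)
        "documents_dedup.csv"
      },
      vectorize = {
        path <- .require_artifact(config, "documents_dedup.csv", "vectorize")
        docs <- .read_documents_artifact(path)
        texts <- setNames(normalize_text(docs$text), docs$admission_id)
        vocab <- build_vocabulary(texts, max_n = config$max_n,
                                  collocation_min_count = config$collocation_min_count,
                                  collocation_threshold = config$collocation_threshold)
        tm <- vectorize_documents(texts, vocab)
        write_term_matrix(tm, .artifact(config, "matrix.mtx"))
        write.csv(docs[, c("admission_id", "group")],
                  .artifact(config, "matrix_groups.csv"), row.names = FALSE)
        c("matrix.mtx", "matrix.vocab.txt", "matrix.docs.txt",
          "matrix_groups.csv")
      },
      select = {
        .require_artifact(config, "matrix.mtx", "select")
        tm <- read_term_matrix(.artifact(config, "matrix.mtx"))
        grp <- read.csv(.artifact(config, "matrix_groups.csv"),
                        stringsAsFactors = FALSE, colClasses = "character")
        groups <- setNames(grp$group, grp$admission_id)[rownames(tm$counts)]
        labels <- if (config$strategy == "ensemble") {
          c(config$target_label, config$comparison_label)
        } else c("period3", "period2")
        split_tm <- function(label) {
          keep <- which(groups == label)
          structure(list(counts = tm$counts[keep, , drop = FALSE],
                         terms = tm$terms), class = "term_matrix")
        }
        res <- if (config$strategy == "ensemble") {
          do.call(select_terms_ensemble,
                  c(list(split_tm(labels[1]), split_tm(labels[2])),
                    config$selection))
        } else {
          do.call(select_terms_temporal,
                  c(list(split_tm("period2"), split_tm("period3")),
                    config$selection))
        }
        writeLines(res$selected, .artifact(config, "selected_terms.txt"))
        write.table(res$diagnostics, .artifact(config, "term_diagnostics.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        c("selected_terms.txt", "term_diagnostics.tsv")
      },
      topics = {
        .require_artifact(config, "matrix.mtx", "topics")
        sel_path <- .require_artifact(config, "selected_terms.txt", "topics")
        tm <- read_term_matrix(.artifact(config, "matrix.mtx"))
        grp <- read.csv(.artifact(config, "matrix_groups.csv"),
                        stringsAsFactors = FALSE, colClasses = "character")
        groups <- setNames(grp$group, grp$admission_id)[rownames(tm$counts)]
        focus <- if (config$strategy == "ensemble") config$target_label else "period3"
        keep <- which(groups == focus)
        tm_focus <- structure(list(counts = tm$counts[keep, , drop = FALSE],
                                   terms = tm$terms), class = "term_matrix")
        trimmed <- trim_matrix(tm_focus, readLines(sel_path))
        model <- fit_lda(trimmed, K = config$K, seed = seed_for("topics"))
        write.table(data.frame(document = rownames(model$doc_topic),
                               model$doc_topic, check.names = FALSE),
                    .artifact(config, "doc_topic.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        write_term_matrix(
          structure(list(counts = as(Matrix::Matrix(model$term_topic,
                                                    sparse = TRUE),
                                     "CsparseMatrix"),
                         terms = colnames(model$term_topic)),
                    class = "term_matrix"),
          .artifact(config, "term_topic.mtx"))
        write.table(summarize_topics(model),
                    .artifact(config, "topic_summary.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        c("doc_topic.tsv", "term_topic.mtx", "topic_summary.tsv")
      },
      review = {
        path <- .require_artifact(config, "doc_topic.tsv", "review")
        dt <- read.csv(path, sep = "\t", check.names = FALSE)
        mat <- as.matrix(dt[, -1, drop = FALSE])
        rownames(mat) <- dt$document
        rs <- select_review_set(mat,
                                top_k = config$review$top_k,
                                sig_threshold = config$review$sig_threshold,
                                n_multi = config$review$n_multi,
                                n_random = min(config$review$n_random, nrow(mat)),
                                seed = seed_for("review"))
        jsonlite::write_json(rs[c("per_topic", "multi_topic", "random", "params")],
                             .artifact(config, "review_set.json"),
                             auto_unbox = FALSE, digits = NA, dataframe = "rows")
        mt <- max_topic_table(mat, sig_threshold = config$review$sig_threshold)
        write.table(data.frame(n_topics = rownames(mt$table), mt$table,
                               check.names = FALSE),
                    .artifact(config, "max_topic_table.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        c("review_set.json", "max_topic_table.tsv")
      },
      trends = {
        path <- .require_artifact(config, "documents_dedup.csv", "trends")
        if (is.null(config$criteria_path)) {
          stopf("stage 'trends' requires criteria_path in the configuration")
        }
        docs <- .read_documents_artifact(path)
        codes <- if (!is.null(config$codes_path)) {
          load_codes(config$codes_path)
        } else if (file.exists(.artifact(config, "codes.csv"))) {
          load_codes(.artifact(config, "codes.csv"))
        } else NULL
        criteria <- load_criteria(config$criteria_path)
        rows <- lapply(names(criteria), function(nm) {
          ts <- fit_trend(quarterly_proportions(docs, criteria[[nm]],
                                                codes = codes))
          cbind(criterion = nm, ts$series,
                slope = ts$fit$slope, ci_lower = ts$fit$ci_lower,
                ci_upper = ts$fit$ci_upper, p_value = ts$fit$p_value)
        })
        write.table(do.call(rbind, rows), .artifact(config, "trends.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        "trends.tsv"
      }
    ))
  }

  files <- file.path(config$out_dir, written)
  manifest <- list(
    package_version = as.character(utils::packageVersion("shakespeare")),
    seed = config$seed,
    strategy = config$strategy,
    stages = stages,
    artifacts = as.list(setNames(unname(tools::md5sum(files)), written))
  )
  jsonlite::write_json(manifest, .artifact(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
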