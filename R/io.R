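read_delim_auto <- function(path) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

warn_extra_cols <- function(df, known, what) {
  extra <- setdiff(names(df), known)
  if (length(extra) > 0L) {
    warning("unknown column(s) in ", what, " ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
}

check_numeric_cols <- function(df, cols, what) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "")
      if (length(bad) > 0L) {
        abort_input(what, ": non-numeric value(s) in column '", col,
                    "' at data row(s) ", paste(bad, collapse = ", "))
      }
      df[[col]] <- vn
    }
  }
  df
}

#' Read a per-isolate trait table from CSV/TSV
#'
#' Delimiter is taken from the extension (`.csv` comma, `.tsv` tab). The
#' file must carry the documented schema (see [trait_table()]); unknown
#' extra columns are accepted with a warning, schema violations (missing
#' columns, duplicate ids, non-numeric cells) are reported with the
#' offending rows.
#'
#' @param path file path.
#' @return a validated [trait_table()].
#' @export
read_trait_table <- function(path) {
  df <- read_delim_auto(path)
  known <- c("isolate_id", "genus", "tissue", "clone", "accession",
             quantitative_traits(), paste0(trait_catalog(), "_positive"))
  warn_extra_cols(df, known, "trait table")
  df <- check_numeric_cols(df, intersect(quantitative_traits(), names(df)),
                           "trait table")
  trait_table(df)
}

#' Read a taxon-by-compartment count table from CSV/TSV
#'
#' First column: taxon labels; remaining columns: one per compartment.
#'
#' @param path file path.
#' @return a `taxon_count_table`.
#' @export
read_taxon_counts <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2L) abort_input("count table needs taxa + >= 1 compartment")
  df <- check_numeric_cols(df, names(df)[-1], "count table")
  taxon_count_table(df)
}

#' Read a long-format growth-trial table from CSV/TSV
#'
#' @param path file path.
#' @return a [growth_trial()].
#' @export
read_growth_table <- function(path) {
  df <- read_delim_auto(path)
  known <- c("clone", "treatment", "replicate", "parameter", "value")
  warn_extra_cols(df, known, "growth table")
  df <- check_numeric_cols(df, intersect(c("replicate", "value"), names(df)),
                           "growth table")
  growth_trial(df[intersect(known, names(df))])
}

#' Write a table as CSV (UTF-8, full precision)
#'
#' @param x data.frame (or matrix with dimnames).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table_csv <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(taxon = rownames(x), as.data.frame(unclass(x)),
                    check.names = FALSE)
  }
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' End-to-end screening report
#'
#' Runs every analysis stage on the supplied inputs and writes a report
#' bundle to `out_dir`: the ranked bonitur score table (`scores.csv`), the
#' per-compartment diversity index table (`diversity.csv`), per-parameter
#' ANOVA tables (`anova.csv`), the fold-change table (`fold_change.csv`),
#' PCA scores and loadings (`pca_scores.csv`, `pca_loadings.csv`), a plain
#' text summary (`summary.txt`) and a provenance record (`provenance.json`:
#' package version, seed, config digest). Any stage failure aborts with a
#' stage-tagged message.
#'
#' @param traits a [trait_table()].
#' @param counts a `taxon_count_table`.
#' @param growth a [growth_trial()], or NULL to skip the growth stage.
#' @param out_dir output directory (created if absent).
#' @param config a [bonitur_config()].
#' @param top_n how many ranked isolates to print in the summary.
#' @param seed seed recorded in provenance (the report itself is
#'   deterministic).
#' @return named character vector of written file paths, invisibly.
#' @export
run_report <- function(traits, counts, growth = NULL, out_dir,
                       config = bonitur_config(), top_n = 10L, seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_input("[stage ", name, "] ", conditionMessage(e))
    })
  }
  paths <- c()

  ranked <- stage("score", rank_isolates(bonitur_score(traits, config)))
  paths["scores"] <- write_table_csv(ranked, file.path(out_dir, "scores.csv"))

  div <- stage("diversity", {
    do.call(rbind, lapply(colnames(counts), function(comp) {
      p <- diversity_profile(counts, comp)
      data.frame(compartment = comp, richness_s = p$richness_s,
                 total_n = p$total_n, shannon_h = p$shannon_h,
                 simpson_d = p$simpson_d, evenness = p$evenness,
                 berger_parker = p$berger_parker, margalef = p$margalef,
                 menhinick = p$menhinick, mean_abundance = p$mean_abundance)
    }))
  })
  paths["diversity"] <- write_table_csv(div, file.path(out_dir, "diversity.csv"))

  if (!is.null(growth)) {
    anova_tab <- stage("anova", {
      do.call(rbind, lapply(unique(growth$parameter), function(p) {
        res <- two_way_anova(growth, p)
        cbind(parameter = p, res$table)
      }))
    })
    paths["anova"] <- write_table_csv(anova_tab, file.path(out_dir, "anova.csv"))

    fc <- stage("fold_change", fold_change_table(growth))
    paths["fold_change"] <- write_table_csv(fc,
                                            file.path(out_dir, "fold_change.csv"))

    pca <- stage("pca", pca_correlation(growth))
    paths["pca_scores"] <- write_table_csv(pca$scores,
                                           file.path(out_dir, "pca_scores.csv"))
    load_df <- data.frame(parameter = rownames(pca$loadings),
                          as.data.frame(unclass(pca$loadings)))
    paths["pca_loadings"] <- write_table_csv(load_df,
                                             file.path(out_dir, "pca_loadings.csv"))
  }

  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  wl <- function(...) writeLines(paste0(...), con)
  wl("Endophyte screening report")
  wl("==========================")
  wl("")
  wl(sprintf("Isolates screened: %d (%s)", nrow(traits),
             paste(sprintf("%s %d", tissue_counts(traits)$tissue,
                           tissue_counts(traits)$count), collapse = ", ")))
  wl("")
  wl(sprintf("Top %d isolates by bonitur score (max %d):",
             min(top_n, nrow(ranked)), config$max_score))
  top <- utils::head(ranked, top_n)
  for (i in seq_len(nrow(top))) {
    wl(sprintf("  %2d. %-8s total %2d (IAA %d, phosphate %d)", top$rank[i],
               top$isolate_id[i], top$total[i], top$iaa_points[i],
               top$phosphate_points[i]))
  }
  wl("")
  wl("Diversity indices per compartment:")
  for (i in seq_len(nrow(div))) {
    wl(sprintf(
      "  %-6s S=%d N=%d H=%s SDI=%s BP=%s Margalef=%s Menhinick=%s N/S=%s",
      div$compartment[i], div$richness_s[i], div$total_n[i],
      round_half_up(div$shannon_h[i], 2), round_half_up(div$simpson_d[i], 3),
      round_half_up(div$berger_parker[i], 3),
      round_half_up(div$margalef[i], 2), round_half_up(div$menhinick[i], 2),
      round_half_up(div$mean_abundance[i], 2)))
  }
  paths["summary"] <- summary_path

  prov <- list(
    package = "pgpscreen",
    version = as.character(utils::packageVersion("pgpscreen")),
    seed = seed,
    n_isolates = nrow(traits),
    bonitur_max_score = config$max_score,
    files = as.list(basename(unlist(paths)))
  )
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE)
  paths["provenance"] <- prov_path

  invisible(paths)
}
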