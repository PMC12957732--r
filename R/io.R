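#' Read a fish metadata CSV
#'
#' Expects columns `id`, `species`, `zone`, `reef`, `length_mm`,
#' `weight_g`, `age_yr` (age may be missing/NA). Validation errors name
#' the offending column and row.
#'
#' @param path Path to a CSV file (lines starting with `#` are ignored).
#' @return Validated data frame of fish records.
#' @export
read_fish_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("id", "species", "zone", "reef", "length_mm", "weight_g",
                "age_yr")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("fish table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("length_mm", "weight_g", "age_yr")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad))
        stop("non-numeric ", col, " at row(s): ",
             paste(head(bad, 5), collapse = ", "),
             " (e.g. '", v[bad[1]], "')", call. = FALSE)
      df[[col]] <- num
    }
  }
  if (any(df$length_mm <= 0, na.rm = TRUE) ||
      any(df$weight_g <= 0, na.rm = TRUE))
    stop("lengths and weights must be strictly positive", call. = FALSE)
  dup <- df$id[duplicated(df$id)]
  if (length(dup))
    stop("duplicate fish id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  df
}

#' Read an OTU read-count table (TSV)
#'
#' One flat TSV dialect: rows are samples, the first column holds sample
#' ids, remaining columns are OTU read counts. `transpose = TRUE` accepts
#' tables written the other way around (rows = OTUs).
#'
#' @param path Path to a TSV file.
#' @param transpose Is the file OTUs x samples?
#' @return Integer matrix, samples x OTUs, rownames = sample ids.
#' @export
read_otu_table <- function(path, transpose = FALSE) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric read counts in ", path, call. = FALSE)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(m < 0)) stop("negative read counts in ", path, call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Read an OTU taxonomy table (TSV)
#'
#' @param path Path to a TSV with column `otu_id` plus rank columns
#'   (`phylum` ... `genus`/`species`).
#' @return Data frame of lineages.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"otu_id" %in% names(df))
    stop("taxonomy table needs an 'otu_id' column", call. = FALSE)
  df
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `fish.csv`, `otu_counts.tsv` (samples as rows), `taxonomy.tsv`,
#' `benthic.csv`, `inverts.csv`, `fish_transects.csv` and `truth.json`
#' (the generating parameters). Every file starts with a provenance
#' comment line recording the package version and seed.
#'
#' @param dataset A [simulate_dataset()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- paste0("# reefdiet ", as.character(packageVersion("reefdiet")),
                   "; seed ", dataset$truth$seed)
  paths <- c(fish = file.path(dir, "fish.csv"),
             otu = file.path(dir, "otu_counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             benthic = file.path(dir, "benthic.csv"),
             inverts = file.path(dir, "inverts.csv"),
             fish_transects = file.path(dir, "fish_transects.csv"),
             truth = file.path(dir, "truth.json"))
  write_with_header <- function(df, path, sep = ",") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  }
  write_with_header(dataset$fish, paths["fish"])
  otu_df <- data.frame(sample_id = rownames(dataset$otu), dataset$otu,
                       check.names = FALSE)
  write_with_header(otu_df, paths["otu"], sep = "\t")
  write_with_header(dataset$taxonomy, paths["taxonomy"], sep = "\t")
  write_with_header(dataset$benthic, paths["benthic"])
  write_with_header(dataset$inverts, paths["inverts"])
  write_with_header(dataset$fish_transects, paths["fish_transects"])
  truth <- dataset$truth
  truth_list <- list(
    seed = truth$seed, zones = truth$zones,
    reefs_per_zone = truth$reefs_per_zone,
    fish_per_reef = truth$fish_per_reef,
    species = lapply(truth$species, function(s) list(
      allometry = s$allometry, weight_sigma = as.list(s$weight_sigma),
      length_sigma = s$length_sigma, ages = s$ages, vbgf = s$vbgf,
      depth = s$depth)),
    diet_alpha = lapply(truth$diet$alpha, function(a)
      as.data.frame(cbind(zone = rownames(a), as.data.frame(a)))),
    cover = truth$surveys$cover)
  jsonlite::write_json(truth_list, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: survey summaries (coral cover, Shannon diversity,
#' densities, zone tests), body condition (length-weight fit, Le Cren
#' K_n, condition-by-zone interaction, lnVR contrasts on its residuals),
#' growth (VBGF fits and zone bootstrap), and diet (phylum aggregation,
#' Bray-Curtis, NMDS, PERMANOVA with pairwise tests, Amundsen
#' feeding-strategy points per zone, and coral-cover GLMMs). Each stage
#' runs per species where applicable, writes plot-ready CSVs to
#' `out_dir`, and is recorded in a manifest with timings and file
#' checksums.
#'
#' @param dataset A [simulate_dataset()] object, or a list with the same
#'   elements read from files.
#' @param out_dir Output directory.
#' @param seed Integer seed governing every stochastic stage.
#' @param boot Bootstrap resamples for lnVR and VBGF (default 1000).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param stages Character vector selecting stages, a subset of
#'   `c("surveys", "condition", "growth", "diet")`.
#' @return Object of class `run_manifest`: per-stage status, outputs,
#'   md5 checksums and timings, plus all in-memory results in
#'   `$results`.
#' @export
run_pipeline <- function(dataset, out_dir, seed = 1L, boot = 1000,
                         n_perm = 999,
                         stages = c("surveys", "condition", "growth",
                                    "diet")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages, several.ok = TRUE)
  manifest <- list(package_version =
                     as.character(packageVersion("reefdiet")),
                   seed = seed, stages = list())
  results <- list()
  species <- unique(dataset$fish$species)
  outfile <- function(name) file.path(out_dir, name)
  record <- function(name, status, files, elapsed, note = NULL) {
    manifest$stages[[name]] <<- list(
      status = status, files = files,
      md5 = if (length(files)) unname(tools::md5sum(files)) else character(),
      seconds = round(elapsed, 3), note = note)
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e) e)
    if (inherits(files, "error")) {
      record(name, "error", character(), proc.time()[["elapsed"]] - t0,
             note = conditionMessage(files))
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(files), call. = FALSE)
    }
    record(name, "ok", files, proc.time()[["elapsed"]] - t0)
  }

  if ("surveys" %in% stages) run_stage("surveys", function() {
    cov <- coral_cover_summary(dataset$benthic)
    results$surveys <<- list(
      cover = cov,
      cover_test = kruskal_epsilon(cov$transect$percent_cover,
                                   cov$transect$zone))
    f1 <- outfile("coral_cover_reef.csv")
    write.csv(cov$reef, f1, row.names = FALSE)
    f2 <- outfile("coral_cover_zone.csv")
    write.csv(cov$zone, f2, row.names = FALSE)
    c(f1, f2)
  })

  if ("condition" %in% stages) run_stage("condition", function() {
    files <- character()
    results$condition <<- list()
    for (sp in species) {
      sub <- dataset$fish[dataset$fish$species == sp, ]
      lw <- fit_length_weight(sub)
      kn <- compute_kn(sub, lw)
      inter <- fit_condition_interaction(kn)
      lnvr <- lnvr_pairwise(inter$residuals$residual,
                            inter$residuals$zone, B = boot, seed = seed)
      results$condition[[sp]] <<- list(lw = lw, kn = kn,
                                       interaction = inter, lnvr = lnvr)
      f1 <- outfile(paste0("condition_", sp, ".csv"))
      write.csv(kn, f1, row.names = FALSE)
      f2 <- outfile(paste0("condition_anova_", sp, ".csv"))
      write.csv(inter$anova, f2, row.names = FALSE)
      f3 <- outfile(paste0("lnvr_", sp, ".csv"))
      write.csv(lnvr, f3, row.names = FALSE)
      files <- c(files, f1, f2, f3)
    }
    files
  })

  if ("growth" %in% stages) run_stage("growth", function() {
    files <- character()
    results$growth <<- list()
    for (sp in species) {
      sub <- dataset$fish[dataset$fish$species == sp &
                            !is.na(dataset$fish$age_yr), ]
      bt <- bootstrap_vbgf(sub$age_yr, sub$length_mm, sub$zone,
                           B = boot, seed = seed, t0 = -2)
      results$growth[[sp]] <<- bt
      f1 <- outfile(paste0("vbgf_", sp, ".csv"))
      write.csv(bt$ci, f1, row.names = FALSE)
      files <- c(files, f1)
    }
    files
  })

  if ("diet" %in% stages) run_stage("diet", function() {
    files <- character()
    results$diet <<- list()
    cover <- coral_cover_summary(dataset$benthic)$reef
    for (sp in species) {
      sub <- dataset$fish[dataset$fish$species == sp, ]
      otu <- dataset$otu[sub$id, , drop = FALSE]
      otu <- otu[, colSums(otu) > 0, drop = FALSE]
      phylum <- aggregate_taxa(otu, dataset$taxonomy, "phylum")
      d <- bray_curtis(otu, mode = "relative")
      nm <- nmds_ord(d, k = 2, seed = seed)
      pm <- permanova(d, sub$zone, n_perm = n_perm, seed = seed)
      pw <- pairwise_permanova(d, sub$zone, n_perm = n_perm, seed = seed)
      am <- lapply(split(seq_len(nrow(sub)), sub$zone), function(idx)
        amundsen(otu[idx, , drop = FALSE]))
      results$diet[[sp]] <<- list(phylum = phylum, nmds = nm,
                                  permanova = pm, pairwise = pw,
                                  amundsen = am)
      f1 <- outfile(paste0("nmds_", sp, ".csv"))
      write.csv(data.frame(sample_id = rownames(nm$points), nm$points,
                           zone = sub$zone), f1, row.names = FALSE)
      f2 <- outfile(paste0("permanova_", sp, ".csv"))
      write.csv(data.frame(f = pm$f, r_squared = pm$r_squared, p = pm$p,
                           n_perm = pm$n_perm), f2, row.names = FALSE)
      f3 <- outfile(paste0("amundsen_", sp, ".csv"))
      am_df <- do.call(rbind, lapply(names(am), function(z)
        cbind(zone = z, as.data.frame(am[[z]]))))
      write.csv(am_df, f3, row.names = FALSE)
      files <- c(files, f1, f2, f3)
    }
    results$diet$glmm <<- local({
      sub <- dataset$fish[dataset$fish$species == species[1], ]
      otu <- dataset$otu[sub$id, , drop = FALSE]
      phylum <- aggregate_taxa(otu, dataset$taxonomy, "phylum")
      if (!"Annelida" %in% colnames(phylum)) return(NULL)
      fit_prey_glmm(phylum[, "Annelida"],
                    cover$mean_cover[match(sub$reef, cover$reef)],
                    sub$zone, sub$reef, depth = rowSums(otu),
                    labels = c(response = "annelid reads",
                               predictor = "coral cover"))
    })
    files
  })

  manifest$results <- results
  skipped <- setdiff(c("surveys", "condition", "growth", "diet"), stages)
  if (length(skipped)) manifest$skipped <- skipped
  json <- manifest
  json$results <- NULL
  jsonlite::write_json(json, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("reefdiet pipeline run (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-10s %-6s %5.2fs  %d file(s)\n", nm, st$status,
                st$seconds, length(st$files)))
  }
  if (!is.null(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
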