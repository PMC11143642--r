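#' Load per-treatment summary statistics
#'
#' Reads the packaged table of per-treatment means and standard deviations
#' (3 cultivars x 4 gibberellic-acid levels x 4 zeatin levels x 4 growth
#' traits, n = 20 replicates per treatment) and validates it against the full
#' factorial design.
#'
#' @param path Path to a CSV with columns
#'   `cultivar, ga3_mg_per_L, zt_mg_per_L, trait, mean, sd, n_rep`. Defaults to
#'   the packaged fixture.
#' @return A validated data.frame of class `treatment_stats` with 192 rows.
#' @export
load_treatment_stats <- function(path = culturopt_extdata("table3_stats.csv")) {
  if (!file.exists(path)) stop("treatment statistics file not found: ", path)
  stats <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cultivar", "ga3_mg_per_L", "zt_mg_per_L", "trait", "mean", "sd", "n_rep")
  missing_cols <- setdiff(required, names(stats))
  if (length(missing_cols)) {
    stop("treatment statistics file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  validate_treatment_stats(stats)
}

validate_treatment_stats <- function(stats) {
  bad_ga3 <- !stats$ga3_mg_per_L %in% GA3_LEVELS
  bad_zt <- !stats$zt_mg_per_L %in% ZT_LEVELS
  if (any(bad_ga3 | bad_zt)) {
    stop("dose levels outside the factorial design in rows: ",
         paste(utils::head(which(bad_ga3 | bad_zt)), collapse = ", "))
  }
  if (any(stats$sd < 0)) {
    stop("negative standard deviation for cell (",
         toString(stats[which(stats$sd < 0)[1],
                        c("cultivar", "ga3_mg_per_L", "zt_mg_per_L", "trait")]), ")")
  }
  es <- stats$trait == "ES"
  if (any(es & (stats$mean < 0 | stats$mean > 100))) {
    stop("explant survival mean outside [0, 100]")
  }
  # completeness: every (cultivar, ga3, zt, trait) cell exactly once
  design <- expand.grid(cultivar = CULTIVARS, ga3_mg_per_L = GA3_LEVELS,
                        zt_mg_per_L = ZT_LEVELS, trait = TRAITS,
                        stringsAsFactors = FALSE)
  key <- function(d) paste(d$cultivar, d$ga3_mg_per_L, d$zt_mg_per_L, d$trait)
  missing_cells <- setdiff(key(design), key(stats))
  if (length(missing_cells)) {
    stop("missing design cell(s) (cultivar ga3 zt trait): ",
         paste(utils::head(missing_cells, 5), collapse = "; "))
  }
  dup <- duplicated(key(stats))
  if (any(dup)) stop("duplicated design cell: ", key(stats)[which(dup)[1]])
  if (nrow(stats) != nrow(design)) stop("expected ", nrow(design), " records, got ", nrow(stats))
  class(stats) <- c("treatment_stats", "data.frame")
  stats
}

#' Regenerate replicate-level observations from summary statistics
#'
#' Draws `n_rep` replicates per treatment cell and trait from a normal
#' distribution with the cell's published mean and standard deviation, clipped
#' to the trait's valid range (survival to \[0, 100\], counts/lengths to
#' \[0, Inf)). Cells with zero standard deviation return the constant mean
#' without consuming random numbers. Each cell uses its own seed substream
#' derived from the root seed and the cell labels, so the draw for a cell does
#' not depend on generation order or on which cultivars are requested.
#'
#' @param stats A `treatment_stats` table (see [load_treatment_stats()]).
#' @param seed Integer root seed; identical seed implies an identical table.
#' @param n_rep Replicates per treatment cell (the study used 20).
#' @param cultivars Cultivars to generate (default: all in `stats`).
#' @return A data.frame of class `observation_table` with columns
#'   `cultivar, ga3_mg_per_L, zt_mg_per_L, LN, PR, ES_pct, SL_cm` and
#'   `n_rep` rows per design cell. The number of values altered by range
#'   clipping is recorded in the `clip_count` attribute.
#' @export
generate_observations <- function(stats, seed, n_rep = 20,
                                  cultivars = unique(stats$cultivar)) {
  stats <- validate_treatment_stats(as.data.frame(stats))
  if (n_rep < 1) stop("n_rep must be >= 1")
  stats <- stats[stats$cultivar %in% cultivars, ]
  cells <- unique(stats[, c("cultivar", "ga3_mg_per_L", "zt_mg_per_L")])
  cells <- cells[order(match(cells$cultivar, CULTIVARS),
                       cells$ga3_mg_per_L, cells$zt_mg_per_L), ]
  clip_count <- 0L
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    out <- data.frame(cultivar = rep(cell$cultivar, n_rep),
                      ga3_mg_per_L = rep(cell$ga3_mg_per_L, n_rep),
                      zt_mg_per_L = rep(cell$zt_mg_per_L, n_rep))
    for (trait in TRAITS) {
      s <- stats[stats$cultivar == cell$cultivar &
                 stats$ga3_mg_per_L == cell$ga3_mg_per_L &
                 stats$zt_mg_per_L == cell$zt_mg_per_L &
                 stats$trait == trait, ]
      if (s$sd == 0) {
        vals <- rep(s$mean, n_rep)
      } else {
        cell_seed <- substream_seed(seed, cell$cultivar, cell$ga3_mg_per_L,
                                    cell$zt_mg_per_L, trait)
        vals <- with_seed(cell_seed, function() stats::rnorm(n_rep, s$mean, s$sd))
        clipped <- clip_trait(vals, trait)
        clip_count <<- clip_count + sum(clipped != vals)
        vals <- clipped
      }
      out[[trait_column(trait)]] <- vals
    }
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "clip_count") <- clip_count
  attr(tab, "seed") <- seed
  class(tab) <- c("observation_table", "data.frame")
  tab
}

#' Write an observation table to CSV
#'
#' @param table An `observation_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observation_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
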