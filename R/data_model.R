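# Domain vocabulary -----------------------------------------------------

#' Controlled vocabularies for land use, tracers and trophic guilds
#'
#' The study design recognises three watershed land uses (forest is the
#' baseline category for all land-use effects), two isotopic tracers
#' (\eqn{\delta^{13}}C vs VPDB and \eqn{\delta^{15}}N vs atmospheric
#' N\eqn{_2}, both in permil), and four consumer trophic guilds.
#'
#' @return Character vector of admitted labels, baseline/reference first.
#' @export
land_use_levels <- function() c("forest", "coffee", "pasture")

#' @rdname land_use_levels
#' @export
tracer_levels <- function() c("d13C", "d15N")

#' @rdname land_use_levels
#' @export
guild_levels <- function() c("detritivore", "herbivore", "omnivore", "carnivore")

# Loose sanity envelopes for bulk tissue values (permil); violations warn.
.d13C_bounds <- c(-60, 0)
.d15N_bounds <- c(-20, 30)

#' Construct an isotope dataset
#'
#' An `isotope_dataset` wraps a data frame of per-individual observations
#' with columns `sample_id`, `category` (`"biofilm"`, `"leaf_litter"`, or
#' `"consumer:<taxon>"`), `guild` (`NA` for resources), `land_use`, `d13C`,
#' `d15N`, plus a provenance string (`"real"` or `"synthetic:<seed>"`).
#'
#' @param observations Data frame with the columns listed above.
#' @param provenance Free-text provenance tag.
#' @return An object of class `isotope_dataset`.
#' @export
isotope_dataset <- function(observations, provenance = "real") {
  required <- c("sample_id", "category", "guild", "land_use", "d13C", "d15N")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols) > 0) {
    stop("observations lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- as.data.frame(observations)[required]
  obs$sample_id <- as.character(obs$sample_id)
  obs$category <- as.character(obs$category)
  obs$guild <- as.character(obs$guild)
  obs$land_use <- as.character(obs$land_use)
  obs$d13C <- as.numeric(obs$d13C)
  obs$d15N <- as.numeric(obs$d15N)

  bad_lu <- setdiff(unique(obs$land_use), land_use_levels())
  if (length(bad_lu) > 0) {
    stop("unknown land_use label(s): ", paste(bad_lu, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(obs$sample_id)) {
    stop("sample_id values must be unique within a dataset", call. = FALSE)
  }
  is_consumer <- startsWith(obs$category, "consumer:")
  bad_cat <- !(is_consumer | obs$category %in% c("biofilm", "leaf_litter"))
  if (any(bad_cat)) {
    stop("unknown category label(s): ",
         paste(unique(obs$category[bad_cat]), collapse = ", "), call. = FALSE)
  }
  bad_guild <- is_consumer & !(obs$guild %in% guild_levels())
  if (any(bad_guild)) {
    stop("consumer rows must carry a guild in {",
         paste(guild_levels(), collapse = ", "), "}", call. = FALSE)
  }

  out_c <- !is.na(obs$d13C) &
    (obs$d13C < .d13C_bounds[1] | obs$d13C > .d13C_bounds[2])
  out_n <- !is.na(obs$d15N) &
    (obs$d15N < .d15N_bounds[1] | obs$d15N > .d15N_bounds[2])
  if (any(out_c)) {
    warning(sum(out_c), " d13C value(s) outside the sanity range [",
            .d13C_bounds[1], ", ", .d13C_bounds[2], "] permil (kept)",
            call. = FALSE)
  }
  if (any(out_n)) {
    warning(sum(out_n), " d15N value(s) outside the sanity range [",
            .d15N_bounds[1], ", ", .d15N_bounds[2], "] permil (kept)",
            call. = FALSE)
  }

  structure(list(observations = obs, provenance = provenance),
            class = "isotope_dataset")
}

#' @export
print.isotope_dataset <- function(x, ...) {
  obs <- x$observations
  cat("<isotope_dataset> ", nrow(obs), " observations (",
      sum(obs$category == "biofilm"), " biofilm, ",
      sum(obs$category == "leaf_litter"), " leaf litter, ",
      sum(startsWith(obs$category, "consumer:")), " consumer)\n", sep = "")
  cat("  land uses: ", paste(sort(unique(obs$land_use)), collapse = ", "),
      "\n  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

# Delimited-text I/O -----------------------------------------------------

#' Read per-individual isotope observations from CSV
#'
#' Expects a comma-separated file with one header row and a "." decimal
#' mark. Column names can be remapped through `schema`. Tracer fields that
#' are empty or `"NA"` are kept as missing values; non-numeric tracer text
#' is an error reporting the offending line numbers.
#'
#' @param path Path to a CSV file with columns `sample_id`, `category`,
#'   `guild` (optional), `land_use`, `d13C`, `d15N`.
#' @param schema Named character vector mapping canonical column names to
#'   the names used in the file, e.g. `c(d13C = "delta13C")`.
#' @return An [isotope_dataset()].
#' @export
read_observations <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) stop("empty dataset: ", path, call. = FALSE)

  canonical <- c("sample_id", "category", "guild", "land_use", "d13C", "d15N")
  for (col in names(schema)) {
    if (!schema[[col]] %in% names(raw)) {
      stop("schema maps ", col, " to absent column ", schema[[col]],
           call. = FALSE)
    }
    names(raw)[names(raw) == schema[[col]]] <- col
  }
  mandatory <- setdiff(canonical, "guild")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0) {
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (!"guild" %in% names(raw)) raw$guild <- NA_character_

  parse_tracer <- function(txt, col) {
    txt <- trimws(txt)
    missing <- is.na(txt) | txt == "" | toupper(txt) == "NA"
    txt[missing] <- NA_character_
    val <- suppressWarnings(as.numeric(txt))
    bad <- !missing & is.na(val)
    if (any(bad)) {
      stop("non-numeric ", col, " value(s) at line(s) ",
           paste(which(bad) + 1L, collapse = ", "), " of ", path,
           call. = FALSE)
    }
    val[missing] <- NA_real_
    val
  }
  raw$d13C <- parse_tracer(raw$d13C, "d13C")
  raw$d15N <- parse_tracer(raw$d15N, "d15N")
  raw$guild[trimws(raw$guild) == ""] <- NA_character_
  isotope_dataset(raw, provenance = "real")
}

#' Write an isotope dataset back to CSV
#'
#' Inverse of [read_observations()]: numeric fields survive a round trip at
#' full printed precision (values are written with `format = "full"` via the
#' default `write.csv` formatting, which prints all significant digits).
#'
#' @param ds An [isotope_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(ds, path) {
  stopifnot(inherits(ds, "isotope_dataset"))
  utils::write.csv(ds$observations, path, row.names = FALSE, na = "NA",
                   quote = FALSE)
  invisible(path)
}

#' Read a printed-style summary table (means, SDs, sample sizes)
#'
#' Reads the layout used for per-category isotopic summaries: one row per
#' category and land use with per-tracer mean, standard deviation, and the
#' number of individuals behind them.
#'
#' @param path CSV with columns `category`, `guild`, `land_use`,
#'   `d13C_mean`, `d13C_sd`, `d15N_mean`, `d15N_sd`, `n`.
#' @return Data frame of summary rows (class `summary_rows`).
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_summary_rows(raw)
}

#' Validate a data frame of summary rows
#'
#' @param rows Data frame with the [read_summary_table()] columns.
#' @return The validated data frame with class `summary_rows` prepended.
#' @export
as_summary_rows <- function(rows) {
  required <- c("category", "land_use", "d13C_mean", "d13C_sd",
                "d15N_mean", "d15N_sd", "n")
  absent <- setdiff(required, names(rows))
  if (length(absent) > 0) {
    stop("summary table lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  rows <- as.data.frame(rows)
  if (!"guild" %in% names(rows)) rows$guild <- NA_character_
  rows$guild[!is.na(rows$guild) & trimws(rows$guild) == ""] <- NA_character_
  rows$n <- as.integer(rows$n)
  if (any(is.na(rows$n)) || any(rows$n <= 0L)) {
    stop("summary rows require integer n >= 1", call. = FALSE)
  }
  for (col in c("d13C_sd", "d15N_sd")) {
    if (any(rows[[col]] < 0)) stop(col, " must be >= 0", call. = FALSE)
    if (any(rows[[col]] == 0)) {
      warning("degenerate spread: ", col, " = 0 in ",
              sum(rows[[col]] == 0), " row(s)", call. = FALSE)
    }
  }
  bad_lu <- setdiff(unique(rows$land_use), land_use_levels())
  if (length(bad_lu) > 0) {
    stop("unknown land_use label(s): ", paste(bad_lu, collapse = ", "),
         call. = FALSE)
  }
  class(rows) <- c("summary_rows", class(rows))
  rows
}

#' Reduce a dataset to per-category summary rows
#'
#' Computes the printed-table reduction: per category x land use, the
#' mean, sd and count of each tracer (missing tracer values excluded).
#' The inverse direction of [generate_from_summary()].
#'
#' @param ds An [isotope_dataset()].
#' @return A `summary_rows` data frame.
#' @export
summarise_dataset <- function(ds) {
  stopifnot(inherits(ds, "isotope_dataset"))
  obs <- ds$observations
  obs$cat_label <- sub("^consumer:", "", obs$category)
  keys <- unique(obs[, c("cat_label", "land_use")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- obs[obs$cat_label == keys$cat_label[i] &
                 obs$land_use == keys$land_use[i], , drop = FALSE]
    c13 <- sub$d13C[!is.na(sub$d13C)]
    n15 <- sub$d15N[!is.na(sub$d15N)]
    data.frame(category = keys$cat_label[i], guild = sub$guild[1],
               land_use = keys$land_use[i],
               d13C_mean = mean(c13),
               d13C_sd = if (length(c13) > 1) stats::sd(c13) else 0,
               d15N_mean = mean(n15),
               d15N_sd = if (length(n15) > 1) stats::sd(n15) else 0,
               n = nrow(sub))
  })
  suppressWarnings(as_summary_rows(do.call(rbind, rows)))
}

# Validation report ------------------------------------------------------

#' Summarise dataset completeness per land use and stage readiness
#'
#' Pure reporting: counts biofilm, leaf-litter and per-taxon consumer
#' observations within each land use, and flags whether stage-1 fitting
#' (needs at least one biofilm and one leaf-litter observation per land
#' use) and stage-2 fitting (needs at least one observation per consumer
#' cell) can proceed.
#'
#' @param ds An [isotope_dataset()].
#' @return A list with `per_land_use` counts, `stage1_ready` flags per land
#'   use, and a `stage2_cells` data frame (taxon, land_use, n). Serialisable
#'   with [jsonlite::toJSON()].
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "isotope_dataset"))
  obs <- ds$observations
  land_uses <- intersect(land_use_levels(), unique(obs$land_use))
  per_lu <- lapply(setNames(land_uses, land_uses), function(lu) {
    sub <- obs[obs$land_use == lu, , drop = FALSE]
    consumers <- sub[startsWith(sub$category, "consumer:"), , drop = FALSE]
    taxa <- table(sub("^consumer:", "", consumers$category))
    list(
      n_biofilm = sum(sub$category == "biofilm"),
      n_leaf_litter = sum(sub$category == "leaf_litter"),
      consumers = as.list(taxa)
    )
  })
  stage1_ready <- vapply(per_lu, function(x) {
    x$n_biofilm >= 1 && x$n_leaf_litter >= 1
  }, logical(1))

  consumers <- obs[startsWith(obs$category, "consumer:"), , drop = FALSE]
  if (nrow(consumers) > 0) {
    tab <- as.data.frame(table(
      taxon = sub("^consumer:", "", consumers$category),
      land_use = consumers$land_use
    ), stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    names(tab)[names(tab) == "Freq"] <- "n"
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(taxon = character(), land_use = character(),
                      n = integer())
  }
  list(per_land_use = per_lu, stage1_ready = as.list(stage1_ready),
       stage2_cells = tab)
}
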