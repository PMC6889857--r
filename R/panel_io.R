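#' Ion-channel identifiers
#'
#' The four cardiac currents used by the net-block score: the
#' repolarizing rapid delayed-rectifier potassium current (`IKr`, the
#' hERG channel) and the three depolarizing currents (late sodium
#' `INaL`, L-type calcium `ICaL`, peak sodium `INa`). The enumeration is
#' closed: unknown channel codes in input files are rejected.
#'
#' @return `bnet_channels()` returns the channel ids in canonical order;
#'   `channel_polarity()` returns `"repolarizing"` or `"depolarizing"`
#'   for each id supplied.
#' @examples
#' bnet_channels()
#' channel_polarity("IKr")
#' @export
bnet_channels <- function() c("IKr", "INaL", "ICaL", "INa")

#' @rdname bnet_channels
#' @param channel character vector of channel ids.
#' @export
channel_polarity <- function(channel) {
  ok <- channel %in% bnet_channels()
  if (!all(ok)) {
    stop("unknown channel id(s): ", paste(channel[!ok], collapse = ", "),
         call. = FALSE)
  }
  ifelse(channel == "IKr", "repolarizing", "depolarizing")
}

RISK_LEVELS <- c("low", "intermediate", "high")
DATASET_LEVELS <- c("training", "validation")

#' Concentration-response summary for one channel
#'
#' A Hill fit holds the half-maximal inhibitory concentration and the
#' Hill coefficient of a drug against one channel. IC50 values reported
#' in the literature as a bound ("> X" when the top concentration tested
#' produced less than half block) are stored at the bound with
#' `ic50_censored = TRUE`; downstream block calculations evaluated at
#' such a bound overestimate block and carry a flag.
#'
#' @param ic50 half-maximal inhibitory concentration, uM; must be a
#'   positive finite number. All concentrations in this package are in
#'   micromolar; no unit auto-detection is performed.
#' @param hill Hill coefficient (dimensionless, > 0), or `NA` when the
#'   source does not report one. A missing Hill is *not* the same as
#'   Hill = 1: block calculations default it to 1 but flag the default.
#' @param ic50_censored logical; `TRUE` when `ic50` is a lower bound.
#' @return an object of class `hill_fit`.
#' @examples
#' hill_fit(2, hill = 1)            # e.g. ibutilide vs hERG
#' hill_fit(50, ic50_censored = TRUE)  # reported as "> 50"
#' @export
hill_fit <- function(ic50, hill = NA_real_, ic50_censored = FALSE) {
  if (!is.numeric(ic50) || length(ic50) != 1L || !is.finite(ic50) || ic50 <= 0)
    stop("ic50 must be a single positive finite number (uM)", call. = FALSE)
  hill <- as.numeric(hill)
  if (length(hill) != 1L)
    stop("hill must be a single number or NA", call. = FALSE)
  if (!is.na(hill) && (!is.finite(hill) || hill <= 0))
    stop("hill, when present, must be positive and finite", call. = FALSE)
  if (!is.logical(ic50_censored) || length(ic50_censored) != 1L ||
      is.na(ic50_censored))
    stop("ic50_censored must be TRUE or FALSE", call. = FALSE)
  structure(list(ic50 = as.numeric(ic50), hill = hill,
                 ic50_censored = ic50_censored),
            class = "hill_fit")
}

#' Dynamic-hERG blocking parameters
#'
#' Parameters of the dynamic hERG description used by the dynamic
#' net-block variant: a dynamic IC50 and the maximal inhibition
#' (fractional ceiling) reached at saturating concentration, optionally
#' with a Hill exponent.
#'
#' @param dyn_ic50 dynamic IC50, uM (> 0, finite).
#' @param max_inhibition maximal fractional inhibition in `[0, 1]`.
#' @param dyn_hill Hill exponent (> 0) or `NA` (defaults to 1 with a
#'   flag when evaluated).
#' @return an object of class `dynamic_herg_fit`.
#' @export
dynamic_herg_fit <- function(dyn_ic50, max_inhibition, dyn_hill = NA_real_) {
  if (!is.numeric(dyn_ic50) || length(dyn_ic50) != 1L ||
      !is.finite(dyn_ic50) || dyn_ic50 <= 0)
    stop("dyn_ic50 must be a single positive finite number (uM)", call. = FALSE)
  if (!is.numeric(max_inhibition) || length(max_inhibition) != 1L ||
      !is.finite(max_inhibition) || max_inhibition < 0 || max_inhibition > 1)
    stop("max_inhibition must be in [0, 1]", call. = FALSE)
  dyn_hill <- as.numeric(dyn_hill)
  if (!is.na(dyn_hill) && (!is.finite(dyn_hill) || dyn_hill <= 0))
    stop("dyn_hill, when present, must be positive and finite", call. = FALSE)
  structure(list(dyn_ic50 = as.numeric(dyn_ic50),
                 max_inhibition = as.numeric(max_inhibition),
                 dyn_hill = dyn_hill),
            class = "dynamic_herg_fit")
}

#' One drug's record in a panel
#'
#' Bundles everything the scoring functions need for one compound: the
#' unbound (free) peak plasma concentration, per-channel Hill fits, and
#' optional risk label, dataset tag, dynamic-hERG parameters and an
#' externally supplied reference metric (e.g. a torsade metric score
#' used only for correlation).
#'
#' @param name drug identifier (non-empty string). Matching elsewhere is
#'   case-insensitive and whitespace-trimmed.
#' @param cmax_free unbound Cmax, uM (> 0), or `NA` when unknown --
#'   records without it can be stored and round-tripped but not scored.
#' @param fits named list of [hill_fit()] objects keyed by channel id
#'   (any subset of `bnet_channels()`, at most one fit per channel).
#' @param risk `"low"`, `"intermediate"`, `"high"` or `NA`.
#' @param dataset `"training"`, `"validation"` or `NA`.
#' @param dynamic_herg a [dynamic_herg_fit()] or `NULL`.
#' @param external_metric numeric or `NA`; an external continuous metric
#'   carried alongside for evaluation (never used in scoring).
#' @param meta named list of free-text metadata (e.g. cell model,
#'   temperature, technique); carried through I/O, never computed on.
#' @return an object of class `drug_record`.
#' @examples
#' drug_record("ibutilide", cmax_free = 0.1,
#'             fits = list(IKr = hill_fit(2, 1)))
#' @export
drug_record <- function(name, cmax_free = NA_real_, fits = list(),
                        risk = NA_character_, dataset = NA_character_,
                        dynamic_herg = NULL, external_metric = NA_real_,
                        meta = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop("drug name must be a non-empty string", call. = FALSE)
  cmax_free <- as.numeric(cmax_free)
  if (!is.na(cmax_free) && (!is.finite(cmax_free) || cmax_free <= 0))
    stop("cmax_free must be positive and finite (uM) for drug '", name, "'",
         call. = FALSE)
  if (length(fits)) {
    if (is.null(names(fits)) || anyNA(names(fits)) || any(!nzchar(names(fits))))
      stop("fits must be a named list keyed by channel id", call. = FALSE)
    bad <- setdiff(names(fits), bnet_channels())
    if (length(bad))
      stop("unknown channel id(s) for drug '", name, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(names(fits)))
      stop("at most one fit per channel for drug '", name, "'", call. = FALSE)
    lapply(fits, function(f) {
      if (!inherits(f, "hill_fit"))
        stop("every fit must be a hill_fit object", call. = FALSE)
    })
  }
  risk <- as.character(risk)
  if (!is.na(risk) && !risk %in% RISK_LEVELS)
    stop("risk must be one of ", paste(RISK_LEVELS, collapse = "/"),
         " for drug '", name, "'", call. = FALSE)
  dataset <- as.character(dataset)
  if (!is.na(dataset) && !dataset %in% DATASET_LEVELS)
    stop("dataset must be training or validation for drug '", name, "'",
         call. = FALSE)
  if (!is.null(dynamic_herg) && !inherits(dynamic_herg, "dynamic_herg_fit"))
    stop("dynamic_herg must be a dynamic_herg_fit or NULL", call. = FALSE)
  external_metric <- as.numeric(external_metric)
  if (!is.na(external_metric) && !is.finite(external_metric))
    stop("external_metric must be finite or NA", call. = FALSE)
  structure(list(name = name, cmax_free = cmax_free, fits = fits,
                 risk = risk, dataset = dataset, dynamic_herg = dynamic_herg,
                 external_metric = external_metric, meta = meta),
            class = "drug_record")
}

#' A panel of drugs
#'
#' An ordered collection of [drug_record()] objects with unique names
#' (case-insensitive, whitespace-trimmed). This is the universal input
#' to scoring and evaluation.
#'
#' @param drugs list of `drug_record` objects.
#' @return an object of class `drug_panel`.
#' @export
drug_panel <- function(drugs = list()) {
  lapply(drugs, function(d) {
    if (!inherits(d, "drug_record"))
      stop("all panel elements must be drug_record objects", call. = FALSE)
  })
  keys <- vapply(drugs, function(d) tolower(trimws(d$name)), character(1))
  if (anyDuplicated(keys))
    stop("duplicate drug name(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  structure(list(drugs = drugs), class = "drug_panel")
}

#' @export
length.drug_panel <- function(x) length(x$drugs)

#' @export
print.drug_panel <- function(x, ...) {
  n <- length(x$drugs)
  cat(sprintf("<drug_panel> %d drug%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    nm <- vapply(x$drugs, `[[`, character(1), "name")
    nch <- vapply(x$drugs, function(d) length(d$fits), integer(1))
    risk <- vapply(x$drugs, `[[`, character(1), "risk")
    cat(sprintf("  %-20s fits=%d risk=%s\n", utils::head(nm, 10),
                utils::head(nch, 10), utils::head(risk, 10)), sep = "")
    if (n > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Look up one drug in a panel by name
#'
#' @param panel a [drug_panel()].
#' @param name drug name; matched case-insensitively, whitespace-trimmed.
#' @return the matching `drug_record`, or `NULL` if absent.
#' @export
panel_drug <- function(panel, name) {
  stopifnot(inherits(panel, "drug_panel"))
  key <- tolower(trimws(name))
  for (d in panel$drugs) if (tolower(trimws(d$name)) == key) return(d)
  NULL
}

# Columns of the long-format panel CSV, in canonical order. One row is
# one drug-channel fit; per-drug fields must agree across a drug's rows.
PANEL_COLUMNS <- c("drug", "channel", "ic50_uM", "ic50_censored", "hill",
                   "cmax_free_uM", "risk", "dataset", "dyn_ic50_uM",
                   "dyn_max_inhib", "dyn_hill", "external_metric")
PANEL_REQUIRED <- c("drug", "channel", "ic50_uM")

# shortest decimal string that reads back to exactly the same double
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    for (d in 15:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

parse_num <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(NA_real_)
  suppressWarnings(v <- as.numeric(s))
  if (is.na(v)) stop("not a number: '", s, "'", call. = FALSE)
  v
}

parse_bool <- function(s, default = FALSE) {
  s <- tolower(trimws(s))
  if (!nzchar(s)) return(default)
  if (s %in% c("true", "t", "1", "yes")) return(TRUE)
  if (s %in% c("false", "f", "0", "no")) return(FALSE)
  stop("not a logical: '", s, "'", call. = FALSE)
}

parse_enum <- function(s, levels, what) {
  s <- tolower(trimws(s))
  if (!nzchar(s)) return(NA_character_)
  if (!s %in% levels)
    stop(what, " must be one of ", paste(levels, collapse = "/"),
         ", got '", s, "'", call. = FALSE)
  s
}

#' Read a drug panel from a long-format CSV
#'
#' One row per drug-channel fit. The documented schema (UTF-8, comma
#' separated, header required) is:
#' `drug, channel (IKr|INaL|ICaL|INa), ic50_uM, ic50_censored
#' (true|false, default false), hill (blank = absent), cmax_free_uM,
#' risk (low|intermediate|high, blank ok), dataset (training|validation,
#' blank ok), dyn_ic50_uM, dyn_max_inhib, dyn_hill, external_metric`.
#' Per-drug fields (`cmax_free_uM`, `risk`, `dataset`, the `dyn_*`
#' fields, `external_metric`) must agree across a drug's rows;
#' disagreement is a validation error. Columns beyond the schema are
#' carried as free-text per-drug metadata. Missing optional columns are
#' treated as all-blank; a missing required column is a schema error.
#'
#' @param path path to the CSV file.
#' @param strict logical. In strict mode (default) any malformed row
#'   aborts the read; in lenient mode malformed rows (and drugs with
#'   internally inconsistent per-drug fields) are skipped with a warning
#'   that names the offending row numbers.
#' @return a validated [drug_panel()].
#' @seealso [write_panel()], [table1_fixture()]
#' @export
read_panel <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing_req <- setdiff(PANEL_REQUIRED, names(raw))
  if (length(missing_req))
    stop("schema error: missing required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  for (col in setdiff(PANEL_COLUMNS, names(raw)))
    raw[[col]] <- character(nrow(raw))
  extra_cols <- setdiff(names(raw), PANEL_COLUMNS)

  n <- nrow(raw)
  if (n == 0L) return(drug_panel())

  bad_rows <- integer(0)
  bad_msgs <- character(0)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      r <- raw[i, , drop = FALSE]
      drug <- trimws(r$drug)
      if (!nzchar(drug)) stop("blank drug name", call. = FALSE)
      channel <- trimws(r$channel)
      if (!channel %in% bnet_channels())
        stop("unknown channel '", channel, "'", call. = FALSE)
      ic50 <- parse_num(r$ic50_uM)
      if (is.na(ic50)) stop("ic50_uM is required", call. = FALSE)
      fit <- hill_fit(ic50, hill = parse_num(r$hill),
                      ic50_censored = parse_bool(r$ic50_censored))
      list(drug = drug, channel = channel, fit = fit,
           cmax = parse_num(r$cmax_free_uM),
           risk = parse_enum(r$risk, RISK_LEVELS, "risk"),
           dataset = parse_enum(r$dataset, DATASET_LEVELS, "dataset"),
           dyn_ic50 = parse_num(r$dyn_ic50_uM),
           dyn_max_inhib = parse_num(r$dyn_max_inhib),
           dyn_hill = parse_num(r$dyn_hill),
           external_metric = parse_num(r$external_metric),
           meta = lapply(r[extra_cols], trimws))
    }, error = function(e) {
      msg <- sprintf("row %d: %s", i + 1L, conditionMessage(e))
      if (strict)
        stop("validation error in ", path, " (", msg, ")", call. = FALSE)
      bad_rows <<- c(bad_rows, i)
      bad_msgs <<- c(bad_msgs, msg)
      NULL
    })
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(bad_rows))
    warning("skipped ", length(bad_rows), " malformed row(s): ",
            paste(bad_msgs, collapse = "; "), call. = FALSE)

  keys <- vapply(rows, function(r) tolower(r$drug), character(1))
  drugs <- list()
  dropped <- character(0)
  for (key in unique(keys)) {
    grp <- rows[keys == key]
    rec <- tryCatch({
      chans <- vapply(grp, `[[`, character(1), "channel")
      if (anyDuplicated(chans))
        stop("duplicate (drug, channel) rows for '", grp[[1]]$drug, "': ",
             paste(chans[duplicated(chans)], collapse = ", "), call. = FALSE)
      per_drug_field <- function(field) {
        vals <- lapply(grp, `[[`, field)
        uniq <- unique(vals)
        if (length(uniq) > 1L)
          stop("per-drug field '", field, "' disagrees across rows of '",
               grp[[1]]$drug, "'", call. = FALSE)
        uniq[[1]]
      }
      cmax <- per_drug_field("cmax")
      if (!is.na(cmax) && cmax <= 0)
        stop("cmax_free_uM must be positive for '", grp[[1]]$drug, "'",
             call. = FALSE)
      dyn_ic50 <- per_drug_field("dyn_ic50")
      dyn_mi <- per_drug_field("dyn_max_inhib")
      dyn_hill <- per_drug_field("dyn_hill")
      dyn <- NULL
      if (!is.na(dyn_ic50) || !is.na(dyn_mi)) {
        if (is.na(dyn_ic50) || is.na(dyn_mi))
          stop("dynamic hERG needs both dyn_ic50_uM and dyn_max_inhib for '",
               grp[[1]]$drug, "'", call. = FALSE)
        dyn <- dynamic_herg_fit(dyn_ic50, dyn_mi, dyn_hill)
      }
      fits <- lapply(grp, `[[`, "fit")
      names(fits) <- chans
      drug_record(grp[[1]]$drug, cmax_free = cmax, fits = fits,
                  risk = per_drug_field("risk"),
                  dataset = per_drug_field("dataset"),
                  dynamic_herg = dyn,
                  external_metric = per_drug_field("external_metric"),
                  meta = grp[[1]]$meta)
    }, error = function(e) {
      if (strict)
        stop("validation error in ", path, ": ", conditionMessage(e),
             call. = FALSE)
      dropped <<- c(dropped, grp[[1]]$drug)
      NULL
    })
    if (!is.null(rec)) drugs <- c(drugs, list(rec))
  }
  if (length(dropped))
    warning("dropped inconsistent drug(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  drug_panel(drugs)
}

#' Write a drug panel to the long-format CSV schema
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(p, f))` reproduces
#' `p` field-for-field, including censoring flags and the distinction
#' between a missing Hill coefficient and Hill = 1 (missing values are
#' written as empty cells, never as 0). Numbers are written with the
#' shortest decimal representation that round-trips exactly.
#'
#' @param panel a [drug_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "drug_panel"))
  rows <- list()
  for (d in panel$drugs) {
    dyn <- d$dynamic_herg
    for (ch in names(d$fits)) {
      f <- d$fits[[ch]]
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d$name, channel = ch,
        ic50_uM = fmt_num(f$ic50),
        ic50_censored = if (f$ic50_censored) "true" else "false",
        hill = fmt_num(f$hill),
        cmax_free_uM = fmt_num(d$cmax_free),
        risk = if (is.na(d$risk)) "" else d$risk,
        dataset = if (is.na(d$dataset)) "" else d$dataset,
        dyn_ic50_uM = fmt_num(if (is.null(dyn)) NA_real_ else dyn$dyn_ic50),
        dyn_max_inhib = fmt_num(if (is.null(dyn)) NA_real_ else dyn$max_inhibition),
        dyn_hill = fmt_num(if (is.null(dyn)) NA_real_ else dyn$dyn_hill),
        external_metric = fmt_num(d$external_metric),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(character(0), 0, length(PANEL_COLUMNS)),
                                  stringsAsFactors = FALSE), PANEL_COLUMNS)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path, call. = FALSE)
  invisible(path)
}

#' hERG literature panel for the 16 CiPA validation drugs
#'
#' Returns the packaged transcription of the literature hERG (IKr) IC50
#' and Hill coefficients for the 16 CiPA validation drugs, one IKr fit
#' per drug. Unbound Cmax is not part of this table, so the records are
#' incomplete for scoring until a Cmax is supplied; nifedipine's IC50 is
#' a censored bound ("> 50"), and nifedipine, nitrendipine and
#' loratadine have no reported Hill coefficient (stored as absent, not
#' 1). Cell model, source, temperature and technique are carried as
#' free-text metadata only.
#'
#' @return a [drug_panel()] of 16 drugs.
#' @examples
#' p <- table1_fixture()
#' panel_drug(p, "Domperidone")$fits$IKr
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "herg_validation_panel.csv",
                      package = "bnetscore", mustWork = TRUE)
  read_panel(path, strict = TRUE)
}
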