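#' Net channel block score for one drug
#'
#' The net-block score is the difference between repolarizing and
#' depolarizing channel block, evaluated at a multiple of the unbound
#' Cmax:
#' \deqn{B_{net} = \sum_i R_i - \sum_j D_j}
#' where \eqn{R_i} is the percent block of the repolarizing current
#' (IKr) and \eqn{D_j} the percent blocks of the depolarizing currents
#' (INaL, ICaL, INa). Higher scores indicate more net repolarization
#' block and therefore higher predicted torsadogenic risk; that
#' orientation is fixed here and consumed, never re-derived, by the
#' evaluation functions. Channels without a fit contribute 0 and are
#' reported in `missing_channels` rather than silently absorbed, so
#' hERG-only screening records remain scorable but visibly incomplete.
#'
#' The default `multiple = 5` is the headline choice after screening 1x,
#' 5x and 10x Cmax; 1x and 10x remain available through the argument.
#' `channels` and `ignore_hill` expose the knobs that separate this
#' score from its original form (which used Hill = 1 everywhere, no INa
#' term, and 1x Cmax): `bnet(d, multiple = 1, channels = c("IKr",
#' "INaL", "ICaL"), ignore_hill = TRUE)` reproduces that variant.
#'
#' @param drug a [drug_record()] with `cmax_free` and an IKr fit.
#' @param multiple positive multiple of the unbound Cmax at which block
#'   is evaluated (default 5).
#' @param channels subset of [bnet_channels()] to evaluate; must include
#'   `"IKr"` (the score is undefined without the repolarizing term).
#' @param ignore_hill logical; if `TRUE`, every Hill coefficient is
#'   forced to 1 (no `hill_defaulted` flag is raised by the forcing).
#' @return an object of class `bnet_result`: list with `drug`,
#'   `variant` (`"static"`), `multiple`, `bnet`, `channel_blocks` (named
#'   numeric over evaluated channels), `missing_channels`, `flags`.
#' @examples
#' d <- drug_record("ex", cmax_free = 0.4,
#'                  fits = list(IKr = hill_fit(2, 1)))
#' bnet(d, multiple = 5)$bnet   # 50: C = 5 * 0.4 = IC50
#' @export
bnet <- function(drug, multiple = 5, channels = bnet_channels(),
                 ignore_hill = FALSE) {
  stopifnot(inherits(drug, "drug_record"))
  if (!is.numeric(multiple) || length(multiple) != 1L ||
      !is.finite(multiple) || multiple <= 0)
    stop("multiple must be a single positive number", call. = FALSE)
  if (!all(channels %in% bnet_channels()) || !"IKr" %in% channels)
    stop("channels must be a subset of bnet_channels() containing IKr",
         call. = FALSE)
  if (is.na(drug$cmax_free))
    stop("incomplete record: drug '", drug$name, "' has no cmax_free",
         call. = FALSE)
  if (!"IKr" %in% names(drug$fits))
    stop("drug '", drug$name,
         "' has no IKr fit; the net-block score is undefined without ",
         "the repolarizing term", call. = FALSE)
  conc <- multiple * drug$cmax_free
  fitted <- intersect(channels, names(drug$fits))
  blocks <- numeric(0)
  flags <- character(0)
  for (ch in fitted) {
    f <- drug$fits[[ch]]
    if (ignore_hill) f <- hill_fit(f$ic50, 1, f$ic50_censored)
    b <- percent_block(conc, f)
    blocks[ch] <- b$percent_block
    flags <- union(flags, b$flags)
  }
  signs <- ifelse(channel_polarity(fitted) == "repolarizing", 1, -1)
  structure(list(drug = drug$name, variant = "static", multiple = multiple,
                 bnet = sum(signs * blocks), channel_blocks = blocks,
                 missing_channels = setdiff(channels, fitted),
                 flags = flags),
            class = "bnet_result")
}

#' Net block with dynamic hERG at 1x Cmax
#'
#' Replaces the static IKr term with the dynamic-hERG block (Emax-scaled
#' Hill, see [dynamic_percent_block()]) evaluated at 1x the unbound
#' Cmax; the depolarizing terms stay static, also at 1x Cmax. No
#' mixed-multiple variant exists: the dynamic parameters are defined at
#' the therapeutic concentration.
#'
#' @param drug a [drug_record()] with `cmax_free` and `dynamic_herg`.
#' @return a `bnet_result` with `variant = "dynamic"` and `multiple = 1`.
#' @export
dynamic_bnet <- function(drug) {
  stopifnot(inherits(drug, "drug_record"))
  if (is.na(drug$cmax_free))
    stop("incomplete record: drug '", drug$name, "' has no cmax_free",
         call. = FALSE)
  if (is.null(drug$dynamic_herg))
    stop("incomplete record: drug '", drug$name,
         "' has no dynamic hERG parameters", call. = FALSE)
  conc <- drug$cmax_free
  herg <- dynamic_percent_block(conc, drug$dynamic_herg)
  blocks <- c(IKr = herg$percent_block)
  flags <- herg$flags
  depol <- intersect(setdiff(bnet_channels(), "IKr"), names(drug$fits))
  for (ch in depol) {
    b <- percent_block(conc, drug$fits[[ch]])
    blocks[ch] <- b$percent_block
    flags <- union(flags, b$flags)
  }
  signs <- ifelse(channel_polarity(names(blocks)) == "repolarizing", 1, -1)
  structure(list(drug = drug$name, variant = "dynamic", multiple = 1,
                 bnet = sum(signs * blocks), channel_blocks = blocks,
                 missing_channels = setdiff(bnet_channels(), names(blocks)),
                 flags = flags),
            class = "bnet_result")
}

#' @export
print.bnet_result <- function(x, ...) {
  cat(sprintf("<bnet_result> %s (%s, %gx Cmax): Bnet = %.3f\n",
              x$drug, x$variant, x$multiple, x$bnet))
  if (length(x$channel_blocks))
    cat("  blocks: ", paste(sprintf("%s=%.2f", names(x$channel_blocks),
                                    x$channel_blocks), collapse = "  "), "\n")
  if (length(x$missing_channels))
    cat("  missing:", paste(x$missing_channels, collapse = ", "), "\n")
  if (length(x$flags))
    cat("  flags:  ", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Score every drug in a panel
#'
#' Applies [bnet()] (or [dynamic_bnet()]) to each drug and returns one
#' row per scored drug, sorted by descending score -- most
#' risk-indicative first -- with ties broken alphabetically by drug
#' name. The returned data frame follows the scored-panel CSV schema
#' written by the command-line `score` subcommand.
#'
#' @param panel a [drug_panel()].
#' @param multiple Cmax multiple for the static variant (default 5;
#'   ignored for the dynamic variant, which is defined at 1x).
#' @param variant `"static"` or `"dynamic"`.
#' @param lenient logical; if `TRUE`, drugs that cannot be scored
#'   (missing Cmax, missing IKr fit or dynamic parameters) are skipped
#'   with a warning instead of aborting.
#' @return a data.frame with columns `drug`, `variant`, `multiple`,
#'   `bnet`, `block_IKr`, `block_INaL`, `block_ICaL`, `block_INa`
#'   (NA where the channel has no fit), `missing_channels`, `flags`
#'   (both semicolon-joined), `risk`, `dataset`, `external_metric`.
#'   Zero scorable drugs yield an empty data.frame with a warning.
#' @export
bnet_panel <- function(panel, multiple = 5, variant = c("static", "dynamic"),
                       lenient = FALSE) {
  stopifnot(inherits(panel, "drug_panel"))
  variant <- match.arg(variant)
  rows <- list()
  skipped <- character(0)
  for (d in panel$drugs) {
    res <- tryCatch(
      if (variant == "static") bnet(d, multiple) else dynamic_bnet(d),
      error = function(e) {
        if (!lenient) stop(e)
        skipped <<- c(skipped, sprintf("%s (%s)", d$name,
                                       conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      drug = d$name, variant = res$variant, multiple = res$multiple,
      bnet = res$bnet,
      block_IKr = unname(res$channel_blocks["IKr"]),
      block_INaL = unname(res$channel_blocks["INaL"]),
      block_ICaL = unname(res$channel_blocks["ICaL"]),
      block_INa = unname(res$channel_blocks["INa"]),
      missing_channels = paste(res$missing_channels, collapse = ";"),
      flags = paste(sort(res$flags), collapse = ";"),
      risk = d$risk, dataset = d$dataset,
      external_metric = d$external_metric,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " unscorable drug(s): ",
            paste(skipped, collapse = "; "), call. = FALSE)
  if (!length(rows)) {
    warning("no scorable drugs in panel", call. = FALSE)
    return(data.frame(drug = character(0), variant = character(0),
                      multiple = numeric(0), bnet = numeric(0),
                      block_IKr = numeric(0), block_INaL = numeric(0),
                      block_ICaL = numeric(0), block_INa = numeric(0),
                      missing_channels = character(0), flags = character(0),
                      risk = character(0), dataset = character(0),
                      external_metric = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$bnet, tolower(df$drug)), , drop = FALSE]
  rownames(df) <- NULL
  df
}
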