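# Body-size categories, parsimony ancestral-state reconstruction of size
# bins and osmoregulation, and body-size reduction percentages across nodes.

#' Body-size category bounds
#'
#' The categories, with upper-inclusive bounds in cm: small (0, 150],
#' medium (150, 400], large (400, 700], gigantic (700, Inf). Medium spans
#' all extant species; large reaches the maxima of extant species; gigantic
#' sizes are only known in extinct taxa.
#'
#' @return data frame with columns `bin`, `lower`, `upper`.
#' @export
size_bins <- function() {
  data.frame(bin = c("small", "medium", "large", "gigantic"),
             lower = c(0, 150, 400, 700),
             upper = c(150, 400, 700, Inf),
             stringsAsFactors = FALSE)
}

#' Classify total length into a size category
#'
#' Bounds are upper-inclusive: 150 cm is small, 400 cm is medium, 700 cm is
#' large; anything above 700 cm is gigantic.
#'
#' @param tl_cm numeric vector of total lengths in cm (> 0).
#' @return ordered factor with levels small < medium < large < gigantic.
#' @export
classify_size <- function(tl_cm) {
  if (any(is.na(tl_cm)) || any(tl_cm <= 0))
    .stopf("total lengths must be positive")
  b <- size_bins()
  idx <- findInterval(tl_cm, b$lower, left.open = TRUE) # upper-inclusive
  ## findInterval with left.open counts (lower, upper]; value exactly at a
  ## boundary belongs to the lower bin
  ordered(b$bin[idx], levels = b$bin)
}

#' Discretise lengths into fine bins for ancestral-state plotting
#'
#' Cuts lengths into upper-inclusive classes of `width` cm (default 50 cm,
#' giving labels like `"150-200"`), an ordered character suitable for
#' [asr_bins()].
#'
#' @param tl_cm named numeric vector of mean total lengths (cm) per taxon.
#' @param width bin width in cm.
#' @return named ordered factor of bin labels.
#' @export
bin_lengths <- function(tl_cm, width = 50) {
  if (any(tl_cm <= 0, na.rm = TRUE)) .stopf("total lengths must be positive")
  idx <- ceiling(tl_cm / width)        # upper-inclusive: 200 -> bin (150,200]
  idx[!is.na(tl_cm) & tl_cm %% width == 0 & idx == 0] <- 1L
  top <- max(idx, na.rm = TRUE)
  labels <- paste0((seq_len(top) - 1L) * width, "-", seq_len(top) * width)
  out <- ordered(labels[idx], levels = labels)
  names(out) <- names(tl_cm)
  out
}

## build a one-character matrix over the tree's tips from a named discrete
## trait; absent/NA taxa become missing cells
.trait_matrix <- function(tree, values, levels) {
  cells <- matrix(vector("list", length(tree$tip.label)), ncol = 1)
  rownames(cells) <- tree$tip.label
  for (i in seq_along(tree$tip.label)) {
    v <- values[[tree$tip.label[i]]]
    cells[[i, 1]] <- if (is.null(v) || is.na(v)) integer(0)
                     else match(as.character(v), levels) - 1L
  }
  cells
}

#' Parsimony ancestral reconstruction of ordered size bins
#'
#' Most-parsimonious (MPR) state sets for a discretised body-size character
#' under ordered (Wagner) costs between adjacent bins. Taxa absent from
#' `bins` (or `NA`) are treated as missing and contribute nothing.
#'
#' @param tree rooted `phylo`.
#' @param bins named factor/character vector of bin labels per taxon; if not
#'   an ordered factor, `levels` gives the bin order.
#' @param levels optional character vector fixing the ordered bin levels.
#' @return an `ancestral_state_map` whose states are bin labels.
#' @export
asr_bins <- function(tree, bins, levels = NULL) {
  .check_phylo(tree)
  if (!length(bins)) .stopf("empty trait set")
  levels <- levels %||% (if (is.factor(bins)) base::levels(bins)
                         else sort(unique(as.character(bins))))
  vals <- stats::setNames(as.character(bins), names(bins))
  if (!all(stats::na.omit(vals) %in% levels))
    .stopf("bin values outside the declared levels")
  if (!any(tree$tip.label %in% names(vals)))
    .stopf("no tip of the tree has a bin value")
  cells <- .trait_matrix(tree, vals, levels)
  cm <- character_matrix(cells, ordered = TRUE)
  amap <- mpr_states(tree, cm, 1L)
  out <- lapply(amap, function(s) levels[s + 1L])
  attributes(out) <- attributes(amap)
  out
}

#' Parsimony ancestral reconstruction of a binary character
#'
#' Fitch MPR sets for an unordered (typically binary) character such as
#' osmoregulation coded from salt-gland, isotopic and occurrence proxies.
#' `"unknown"`/`NA` tips are treated as missing.
#'
#' @param tree rooted `phylo`.
#' @param states named character vector per taxon, e.g. values
#'   `"saltwater_tolerant"` / `"freshwater_only"` / `"unknown"`.
#' @param unknown value(s) treated as missing (default `"unknown"`).
#' @return an `ancestral_state_map` whose states are the observed labels.
#' @export
asr_binary <- function(tree, states, unknown = "unknown") {
  .check_phylo(tree)
  vals <- stats::setNames(as.character(states), names(states))
  vals[vals %in% unknown] <- NA
  known <- sort(unique(stats::na.omit(vals)))
  if (!length(known)) .stopf("all tips are unknown")
  cells <- .trait_matrix(tree, vals, known)
  cm <- character_matrix(cells, ordered = FALSE)
  amap <- mpr_states(tree, cm, 1L)
  out <- lapply(amap, function(s) known[s + 1L])
  attributes(out) <- attributes(amap)
  out
}

#' Body-size reduction percentage between two size-bin intervals
#'
#' For an ancestral bin `[la, ua]` and descendant bin `[ld, ud]` (cm), the
#' reduction band relative to the ancestral upper bound:
#' `min = (1 - ud/ua) * 100` and `max = (1 - ld/ua) * 100`. With the
#' 200-250 cm ancestral and 150-200 cm descendant bins this yields the
#' 20-40% band; a descendant shrinking below 150 cm starts at 40%.
#'
#' @param ancestral numeric `c(lower, upper)` of the ancestral bin, cm.
#' @param descendant numeric `c(lower, upper)` of the descendant bin, cm.
#' @return named numeric vector `c(min = , max = )` in percent.
#' @export
reduction_percent <- function(ancestral, descendant) {
  stopifnot(length(ancestral) == 2L, length(descendant) == 2L)
  if (!all(is.finite(c(ancestral, descendant))))
    .stopf("bins must have finite bounds")
  if (ancestral[1] > ancestral[2] || descendant[1] > descendant[2])
    .stopf("bins must be ordered c(lower, upper)")
  if (ancestral[2] <= 0) .stopf("ancestral upper bound must be positive")
  mn <- (1 - descendant[2] / ancestral[2]) * 100
  mx <- (1 - descendant[1] / ancestral[2]) * 100
  if (mn < 0) {
    message("descendant bin exceeds the ancestral bin; minimum reported as 0")
    mn <- 0
  }
  c(min = mn, max = mx)
}
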