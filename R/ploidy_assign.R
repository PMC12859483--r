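# From mixture components to named ploidy classes, per-nucleus calls and
# posterior-based uncertainty intervals.

# "2C" -> list(value = 2, suffix = "C"); "2αC" -> list(2, "αC")
parse_class_name <- function(name) {
  m <- regmatches(name, regexec("^([0-9]+)(.*)$", name))[[1]]
  if (length(m) != 3) stop("cannot parse ladder base class '", name, "'", call. = FALSE)
  list(value = as.numeric(m[2]), suffix = m[3])
}

ladder_names <- function(n, base_class, open_top = FALSE) {
  p <- parse_class_name(base_class)
  vals <- p$value * 2^(seq_len(n) - 1)
  names <- paste0(format(vals, scientific = FALSE, trim = TRUE), p$suffix)
  if (open_top && n >= 1) names[n] <- paste0("≥", names[n])
  names
}

#' Map mixture components to named ploidy classes
#'
#' Components are sorted by ascending mean of the anchor feature (default:
#' the intensity dimension, the DNA-content proxy) and named along a
#' doubling ladder starting at `base_class`. With `drop_lowest`, the
#' lowest-mean component becomes `"<base/Unclassified"` and is excluded
#' from downstream summaries; with `open_top`, the top class is prefixed
#' with a greater-equal sign. When `anchors` (log2 feature rows of nuclei
#' of known ploidy) are given, the component holding the majority of
#' anchors is pinned to `anchors$class`, components with lower means are
#' merged into that class, and the ladder doubles upward from it.
#'
#' @param model a fitted `mixture_model`.
#' @param base_class name of the lowest ladder class, e.g. `"2C"` or a
#'   relative `"2αC"`.
#' @param drop_lowest name the lowest-mean component
#'   `"<base/Unclassified"` and drop it from summaries.
#' @param open_top prefix the highest class with `"≥"`.
#' @param anchor_feature feature (name or column index) whose component
#'   means define the ladder order; default first feature.
#' @param anchors optional `list(X = matrix of log2 features, class =
#'   "2C")` of nuclei with known ploidy.
#' @return a `component_class_map`: `order` (components by ascending
#'   anchor mean), `class_names` (per component, original indexing),
#'   `classes` (ladder order, unique), `drop_classes`, `anchor_feature`.
#' @export
map_components_to_classes <- function(model, base_class = "2C",
                                      drop_lowest = FALSE, open_top = FALSE,
                                      anchor_feature = 1L, anchors = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  K <- model$K
  if (is.character(anchor_feature)) {
    anchor_feature <- match(anchor_feature, model$feature_names)
    if (is.na(anchor_feature)) stop("anchor feature not among model features", call. = FALSE)
  }
  ord <- order(model$means[, anchor_feature])
  rank_of <- match(seq_len(K), ord) # component -> position in sorted order
  class_by_rank <- character(K)
  drop_classes <- character(0)
  if (is.null(anchors)) {
    if (drop_lowest && K >= 2) {
      unc <- paste0("<", base_class, "/Unclassified")
      class_by_rank[1] <- unc
      drop_classes <- unc
      class_by_rank[2:K] <- ladder_names(K - 1, base_class, open_top)
    } else {
      class_by_rank <- ladder_names(K, base_class, open_top)
    }
  } else {
    post <- posteriors(model, anchors$X)
    comp <- max.col(post, ties.method = "first")
    hit_ranks <- sort(unique(rank_of[comp]))
    if (length(hit_ranks) > 1 && any(diff(hit_ranks) > 1)) {
      stop(
        "anchor nuclei span non-adjacent components (sorted positions ",
        paste(hit_ranks, collapse = ", "), "); check the anchor set",
        call. = FALSE
      )
    }
    pin <- rank_of[as.integer(names(which.max(table(comp))))]
    # components at or below the pinned one carry the anchor class
    n_above <- K - pin
    ladder <- ladder_names(n_above + 1, anchors$class, open_top)
    class_by_rank[seq_len(pin)] <- ladder[1]
    if (n_above > 0) class_by_rank[(pin + 1):K] <- ladder[-1]
    if (pin > 1) {
      np_log("class_map", "info", sprintf(
        "%d component(s) below the anchor merged into class %s", pin - 1, ladder[1]
      ))
    }
    if (drop_lowest) {
      np_log(
        "class_map", "warning",
        "drop_lowest ignored when anchors are given (anchor pins the base class)"
      )
    }
  }
  class_names <- class_by_rank[rank_of]
  structure(
    list(
      order = ord,
      class_names = class_names,
      classes = unique(class_by_rank[!class_by_rank %in% drop_classes]),
      drop_classes = drop_classes,
      anchor_feature = anchor_feature,
      anchor_means = model$means[, anchor_feature]
    ),
    class = "component_class_map"
  )
}

#' @export
print.component_class_map <- function(x, ...) {
  cat("<component_class_map>", paste(x$class_names[x$order], collapse = " | "), "\n")
  if (length(x$drop_classes)) {
    cat("  dropped from summaries:", paste(x$drop_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify nuclei from a posterior matrix
#'
#' Assigns each nucleus to the component with the largest posterior
#' (exact ties break toward the lower-mean component — the conservative
#' ploidy call), names it through the class map, and flags confidence:
#' `confident` when the maximum posterior exceeds 0.8, `ambiguous_second`
#' when the second-largest exceeds 0.2. Nuclei falling in a dropped class
#' are flagged `filtered`.
#'
#' @param posterior_matrix n x K responsibility matrix (rows sum to 1).
#' @param class_map a [map_components_to_classes()] result.
#' @param object_ids optional ids carried through to the output.
#' @param index optional mapping of posterior rows to source-table rows
#'   (as produced by [log2_features()]).
#' @param conf_threshold,second_threshold the confidence cutoffs.
#' @return a `ploidy_assignment`: `df` (per-nucleus calls), `posteriors`,
#'   `class_map`, `index`.
#' @export
classify <- function(posterior_matrix, class_map, object_ids = NULL, index = NULL,
                     conf_threshold = 0.8, second_threshold = 0.2) {
  stopifnot(inherits(class_map, "component_class_map"))
  P <- as.matrix(posterior_matrix)
  if (nrow(P) == 0) stop("empty posterior matrix", call. = FALSE)
  K <- ncol(P)
  if (K != length(class_map$class_names)) {
    stop("posterior columns do not match the class map", call. = FALSE)
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-6)) stop("posterior rows must sum to 1", call. = FALSE)
  # argmax with ties toward the lower-mean component: scan in sorted order
  rank_order <- class_map$order
  P_sorted <- P[, rank_order, drop = FALSE]
  k_rank <- max.col(P_sorted, ties.method = "first")
  k_max <- rank_order[k_rank]
  p_max <- P[cbind(seq_len(nrow(P)), k_max)]
  second <- t(apply(P, 1L, function(r) {
    j <- order(r, decreasing = TRUE)[2L]
    c(j, r[j])
  }))
  if (K == 1L) second <- cbind(rep(NA_integer_, nrow(P)), rep(0, nrow(P)))
  cls <- class_map$class_names[k_max]
  df <- data.frame(
    object_id = object_ids %||% rep(NA_integer_, nrow(P)),
    component = k_max,
    class = cls,
    max_posterior = p_max,
    confident = p_max > conf_threshold,
    second_component = as.integer(second[, 1]),
    second_posterior = second[, 2],
    ambiguous_second = second[, 2] > second_threshold,
    filtered = cls %in% class_map$drop_classes,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      df = df, posteriors = P, class_map = class_map, index = index,
      conf_threshold = conf_threshold, second_threshold = second_threshold
    ),
    class = "ploidy_assignment"
  )
}

#' @export
print.ploidy_assignment <- function(x, ...) {
  tab <- table(x$df$class)
  cat(
    "<ploidy_assignment>", nrow(x$df), "nuclei:",
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Per-class proportions with posterior-based uncertainty intervals
#'
#' Implements the uncertainty procedure for ploidy histograms. Over the n
#' non-filtered nuclei: `V^k` is the proportion classified into class k;
#' `C_out^k` the proportion classified into k whose maximum posterior is
#' below `conf_threshold` (strictly, they could leave); `C_in^k` the
#' proportion of all nuclei whose second-largest posterior exceeds
#' `second_threshold` and points at k (they could join); the interval is
#' `(V^k - C_out^k, V^k + C_in^k)`.
#'
#' @param assignment a [classify()] result.
#' @param conf_threshold maximum-posterior confidence cutoff (default 0.8).
#' @param second_threshold second-posterior cutoff (default 0.2).
#' @return a `class_summary` data.frame (class, count, V, C_out, C_in,
#'   lower, upper) with attributes `n` and `K`.
#' @export
uncertainty_intervals <- function(assignment, conf_threshold = 0.8,
                                  second_threshold = 0.2) {
  stopifnot(inherits(assignment, "ploidy_assignment"))
  stopifnot(conf_threshold > 0, conf_threshold < 1, second_threshold > 0, second_threshold < 1)
  keep <- !assignment$df$filtered
  df <- assignment$df[keep, , drop = FALSE]
  P <- assignment$posteriors[keep, , drop = FALSE]
  n <- nrow(df)
  cmap <- assignment$class_map
  classes <- cmap$classes
  comp_class <- cmap$class_names
  out <- data.frame(
    class = classes, count = 0L, V = 0, C_out = 0, C_in = 0,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(classes)) {
    k_members <- df$class == classes[i]
    out$count[i] <- sum(k_members)
    out$V[i] <- sum(k_members) / n
    out$C_out[i] <- sum(k_members & df$max_posterior < conf_threshold) / n
    sec_class <- comp_class[df$second_component]
    pointers <- !is.na(df$second_component) &
      df$second_posterior > second_threshold & sec_class == classes[i]
    out$C_in[i] <- sum(pointers) / n
  }
  out$lower <- out$V - out$C_out
  out$upper <- out$V + out$C_in
  structure(out, n = n, K = length(classes), class = c("class_summary", "data.frame"))
}
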