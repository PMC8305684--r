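# Deterministic, SOM-independent transition calling: a gene belongs to a
# cluster iff it shows the required state in every sample of group A and the
# target state in every sample of group B. Strict all-sample consistency;
# everything else is unclassified.

#' Construct a transition rule
#'
#' @param label Cluster name.
#' @param from_state Two-bit code required in every `group_a` sample.
#' @param to_state Two-bit code required in every `group_b` sample.
#' @param group_a,group_b Character vectors of sample ids. For constant
#'   clusters (a, b) the two groups may be identical with
#'   `from_state == to_state`.
#' @return List of class `transition_rule`.
#' @export
transition_rule <- function(label, from_state, to_state, group_a, group_b) {
  if (!from_state %in% MOD_STATES || !to_state %in% MOD_STATES)
    abort_arg("states must be one of ", paste(MOD_STATES, collapse = ", "))
  if (!length(group_a) || !length(group_b))
    abort_arg("rule groups must be non-empty")
  structure(list(label = label, from_state = from_state, to_state = to_state,
                 group_a = group_a, group_b = group_b),
            class = "transition_rule")
}

check_classes <- function(sample_classes) {
  ok <- c("tissue", "short_term", "long_term")
  if (is.null(names(sample_classes)) || !all(sample_classes %in% ok))
    abort_arg("sample_classes must be a named vector with classes ",
              paste(ok, collapse = ", "))
  sample_classes
}

#' Standard rule set for the eight drift clusters
#'
#' Constant clusters: a = (10) in every sample, b = (01) in every sample.
#' Tissue-to-organoid transitions (group A = tissue, group B = all
#' organoids): c (10)->(00), d (00)->(01), e (11)->(01), f (11)->(10).
#' Long-term-only transitions from [longterm_rules()]: g (11)->(10),
#' h (00)->(10).
#'
#' @param sample_classes Named character vector, sample id -> condition
#'   class (`tissue`, `short_term`, `long_term`).
#' @param include_tissue_in_longterm Whether rules g/h require the
#'   from-state in tissue samples as well as short-term organoids.
#' @return List of `transition_rule`s labelled a--h.
#' @export
standard_rules <- function(sample_classes, include_tissue_in_longterm = TRUE) {
  sample_classes <- check_classes(sample_classes)
  s <- names(sample_classes)
  tissue <- s[sample_classes == "tissue"]
  organoid <- s[sample_classes != "tissue"]
  c(list(
    transition_rule("a", "10", "10", s, s),
    transition_rule("b", "01", "01", s, s),
    transition_rule("c", "10", "00", tissue, organoid),
    transition_rule("d", "00", "01", tissue, organoid),
    transition_rule("e", "11", "01", tissue, organoid),
    transition_rule("f", "11", "10", tissue, organoid)),
    longterm_rules(sample_classes, include_tissue_in_longterm))
}

#' Rules for the long-term-only activations (clusters g and h)
#'
#' g: loss of H3K27me3 at stable H3K4me3 in long-term culture,
#' (11) -> (10); h: gain of H3K4me3 at previously unmodified genes,
#' (00) -> (10). Group A defaults to tissue plus short-term samples, group B
#' is the long-term samples.
#'
#' @inheritParams standard_rules
#' @return List of two `transition_rule`s, g and h.
#' @export
longterm_rules <- function(sample_classes, include_tissue_in_longterm = TRUE) {
  sample_classes <- check_classes(sample_classes)
  s <- names(sample_classes)
  if (!any(sample_classes == "long_term"))
    abort_arg("no long_term samples in sample_classes")
  early <- if (include_tissue_in_longterm)
    s[sample_classes != "long_term"] else s[sample_classes == "short_term"]
  late <- s[sample_classes == "long_term"]
  list(transition_rule("g", "11", "10", early, late),
       transition_rule("h", "00", "10", early, late))
}

#' Call state transitions over a code matrix
#'
#' A gene receives label L iff it has the rule's from-state in every group-A
#' sample and the to-state in every group-B sample; genes matching no rule
#' are `unclassified`. A gene matching two rules is a configuration error
#' and is reported, not silently resolved.
#'
#' @param codes A `code_matrix`.
#' @param rules List of `transition_rule`s.
#' @return Data frame (`gene_id`, `label`) covering every gene in `codes`.
#' @export
call_transitions <- function(codes, rules) {
  labs <- vapply(rules, `[[`, "", "label")
  hit <- vapply(rules, function(r) {
    miss <- setdiff(c(r$group_a, r$group_b), colnames(codes))
    if (length(miss)) abort_arg("rule ", r$label, ": unknown samples ",
                                paste(miss, collapse = ", "))
    rowSums(codes[, r$group_a, drop = FALSE] != r$from_state) == 0 &
      rowSums(codes[, r$group_b, drop = FALSE] != r$to_state) == 0
  }, logical(nrow(codes)))
  hit <- matrix(hit, nrow = nrow(codes))
  n_hit <- rowSums(hit)
  if (any(n_hit > 1)) {
    bad <- which(n_hit > 1)[1]
    abort_arg("overlapping rules: gene ", rownames(codes)[bad], " matches ",
              paste(labs[hit[bad, ]], collapse = " and "))
  }
  label <- rep("unclassified", nrow(codes))
  for (k in seq_along(rules)) label[hit[, k]] <- labs[k]
  data.frame(gene_id = rownames(codes), label = label,
             stringsAsFactors = FALSE)
}

#' Average modification level of a cluster in one sample
#'
#' Mean of one mark's bit over the genes called into a cluster — e.g. the
#' average K27 level of the constant repressed cluster in a given sample.
#'
#' @param calls Output of [call_transitions()].
#' @param codes The `code_matrix` the calls were made on.
#' @param label Cluster label to summarize.
#' @param mark `"K4"` or `"K27"`.
#' @param sample Sample id.
#' @return Fraction in `[0, 1]`, or `NA` with a warning for an empty
#'   cluster.
#' @export
cluster_modification_average <- function(calls, codes, label,
                                         mark = c("K4", "K27"), sample) {
  mark <- match.arg(mark)
  g <- calls$gene_id[calls$label == label]
  if (!length(g)) {
    warning("empty cluster: ", label)
    return(NA_real_)
  }
  bit <- if (mark == "K4") 1L else 2L
  mean(substr(codes[g, sample], bit, bit) == "1")
}
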