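# Perioperative decision tree for ESS: intraoperative death and
# complication, postoperative complication type (infection, epistaxis,
# CSF leak) and its management, yielding path probabilities and one-time
# costs before Markov entry.

#' Construct a chance node
#'
#' @param label Node label.
#' @param branches List of branches, each a list with elements `prob`
#'   (numeric probability), `prob_name` (optional parameter name, for
#'   audit) and `node` (a `chance_node` or `terminal_node`).
#' @return Object of class `chance_node`.
#' @export
chance_node <- function(label, branches) {
  probs <- vapply(branches, function(b) b$prob, numeric(1))
  if (any(probs < 0)) stop("negative branch probability at node '", label, "'")
  if (abs(sum(probs) - 1) > 1e-9) {
    stop(sprintf("branch probabilities at node '%s' sum to %.6f, not 1",
                 label, sum(probs)))
  }
  structure(list(label = label, branches = branches), class = "chance_node")
}

#' Construct a terminal node
#'
#' @param label Leaf label.
#' @param cost Total one-time cost accrued along the path (USD).
#' @param cost_items Named numeric vector of the cost components, for
#'   audit.
#' @param disposition `"enter_markov"` or `"death"`. A death terminal
#'   never enters the Markov model.
#' @return Object of class `terminal_node`.
#' @export
terminal_node <- function(label, cost, cost_items = NULL,
                          disposition = c("enter_markov", "death")) {
  disposition <- match.arg(disposition)
  stopifnot(is.numeric(cost), length(cost) == 1, cost >= 0)
  structure(list(label = label, cost = cost, cost_items = cost_items,
                 disposition = disposition), class = "terminal_node")
}

branch <- function(prob, node, prob_name = NA_character_) {
  list(prob = as.numeric(prob), prob_name = prob_name, node = node)
}

#' Build the perioperative decision tree for ESS
#'
#' Structure: surgical death (pDeath, cost cESS + cDeath) versus
#' survival; survivors face an intraoperative-complication node
#' (pIntraOpComp, incremental cost cESSMajorComp) and then — whether or
#' not an intraoperative complication occurred — a postoperative node:
#' no complication, or a complication whose type is infection
#' (cInfection), epistaxis (conservative cBleedCons / operative
#' cBleedOR) or CSF leak (conservative cCSFCons / operative cCSFOR).
#' Every path carries the surgery cost cESS. All non-death leaves enter
#' the Markov model.
#'
#' @param params A `parameter_set` (complementary groups already
#'   normalized, so sibling probabilities sum to 1).
#' @return The root `chance_node`.
#' @export
build_perioperative_tree <- function(params) {
  pv <- function(nm) unname(param_value(params, nm))
  cESS <- pv("cESS")

  leaf <- function(label, extra, disposition = "enter_markov") {
    items <- c(cESS = cESS, extra)
    terminal_node(label, cost = sum(items), cost_items = items,
                  disposition = disposition)
  }
  # postoperative subtree, shared shape; `prefix`/`extra` mark whether an
  # intraoperative complication already occurred
  postop_subtree <- function(prefix, extra) {
    type_node <- chance_node(paste0(prefix, "postop complication type"), list(
      branch(pv("pPostOpInfection"),
             leaf(paste0(prefix, "infection"),
                  c(extra, cInfection = pv("cInfection"))),
             "pPostOpInfection"),
      branch(pv("pPostOpEpistaxis"),
             chance_node(paste0(prefix, "epistaxis management"), list(
               branch(pv("pPostOpEpistaxisCons"),
                      leaf(paste0(prefix, "epistaxis, conservative"),
                           c(extra, cBleedCons = pv("cBleedCons"))),
                      "pPostOpEpistaxisCons"),
               branch(pv("pPostOpEpistaxisOR"),
                      leaf(paste0(prefix, "epistaxis, OR"),
                           c(extra, cBleedOR = pv("cBleedOR"))),
                      "pPostOpEpistaxisOR"))),
             "pPostOpEpistaxis"),
      branch(pv("pPostOpCSFleak"),
             chance_node(paste0(prefix, "CSF leak management"), list(
               branch(pv("pPostOpCSFleakCons"),
                      leaf(paste0(prefix, "CSF leak, conservative"),
                           c(extra, cCSFCons = pv("cCSFCons"))),
                      "pPostOpCSFleakCons"),
               branch(pv("pPostOpCSFleakOR"),
                      leaf(paste0(prefix, "CSF leak, OR"),
                           c(extra, cCSFOR = pv("cCSFOR"))),
                      "pPostOpCSFleakOR"))),
             "pPostOpCSFleak")))
    chance_node(paste0(prefix, "postoperative complication?"), list(
      branch(pv("pNoPostOpComp"),
             leaf(paste0(prefix, "no postop complication"), extra),
             "pNoPostOpComp"),
      branch(pv("pPostOpComp"), type_node, "pPostOpComp")))
  }

  intraop <- chance_node("intraoperative complication?", list(
    branch(pv("pNoIntraOpComp"), postop_subtree("", NULL), "pNoIntraOpComp"),
    branch(pv("pIntraOpComp"),
           postop_subtree("intraop complication + ",
                          c(cESSMajorComp = pv("cESSMajorComp"))),
           "pIntraOpComp")))

  chance_node("ESS", list(
    branch(pv("pDeath"),
           terminal_node("perioperative death",
                         cost = cESS + pv("cDeath"),
                         cost_items = c(cESS = cESS, cDeath = pv("cDeath")),
                         disposition = "death"),
           "pDeath"),
    branch(1 - pv("pDeath"), intraop)))
}

#' Enumerate all terminal outcomes of a decision tree
#'
#' Exhaustive depth-first leaf enumeration with multiplied path
#' probabilities; probabilities over all outcomes sum to 1.
#'
#' @param tree A `chance_node` or `terminal_node`.
#' @return Data frame with columns `label`, `probability`, `cost`,
#'   `disposition`.
#' @export
enumerate_outcomes <- function(tree) {
  walk <- function(node, p, depth) {
    if (depth > 64) stop("tree depth exceeds 64; is the structure cyclic?")
    if (inherits(node, "terminal_node")) {
      return(data.frame(label = node$label, probability = p,
                        cost = node$cost, disposition = node$disposition))
    }
    if (!inherits(node, "chance_node")) stop("malformed tree node")
    do.call(rbind, lapply(node$branches,
                          function(b) walk(b$node, p * b$prob, depth + 1)))
  }
  out <- walk(tree, 1, 0)
  rownames(out) <- NULL
  out
}

#' Expected one-time cost of traversing a decision tree
#'
#' @param tree A `chance_node` or `terminal_node`.
#' @return Probability-weighted sum of outcome costs (USD).
#' @export
expected_perioperative_cost <- function(tree) {
  out <- enumerate_outcomes(tree)
  sum(out$probability * out$cost)
}

#' Sample outcomes from a decision tree
#'
#' Draws leaves with their path probabilities, using the current RNG
#' state (seed management belongs to the caller).
#'
#' @param tree A `chance_node` or `terminal_node`.
#' @param n Number of draws.
#' @return Data frame of `n` sampled rows of [enumerate_outcomes()].
#' @export
sample_outcome <- function(tree, n = 1) {
  out <- enumerate_outcomes(tree)
  idx <- sample.int(nrow(out), size = n, replace = TRUE, prob = out$probability)
  out[idx, , drop = FALSE]
}

#' Export a decision tree to JSON for audit
#'
#' @param tree A `chance_node` or `terminal_node`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    if (inherits(node, "terminal_node")) {
      list(type = "terminal", label = node$label, cost = node$cost,
           cost_items = as.list(node$cost_items),
           disposition = node$disposition)
    } else {
      list(type = "chance", label = node$label,
           branches = lapply(node$branches, function(b) {
             list(prob = b$prob, prob_name = b$prob_name,
                  node = strip(b$node))
           }))
    }
  }
  js <- jsonlite::toJSON(strip(tree), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Import a decision tree from JSON
#'
#' @param path File path or JSON string produced by [tree_to_json()].
#' @return The reconstructed tree.
#' @export
tree_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rebuild <- function(o) {
    if (o$type == "terminal") {
      terminal_node(o$label, cost = o$cost,
                    cost_items = unlist(o$cost_items),
                    disposition = o$disposition)
    } else {
      chance_node(o$label, lapply(o$branches, function(b) {
        branch(b$prob, rebuild(b$node),
               prob_name = if (is.null(b$prob_name)) NA_character_ else b$prob_name)
      }))
    }
  }
  rebuild(obj)
}

#' @export
print.chance_node <- function(x, ...) {
  out <- enumerate_outcomes(x)
  cat(sprintf("<chance_node> '%s': %d terminal outcomes\n", x$label, nrow(out)))
  cat(sprintf("  expected one-time cost: $%.2f\n",
              sum(out$probability * out$cost)))
  print(out, row.names = FALSE, digits = 6)
  invisible(x)
}
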