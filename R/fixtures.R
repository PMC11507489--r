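#' Five-node benchmark network
#'
#' The classic smoking-history diagnosis network (after Neapolitan's
#' textbook example): binary variables H (smoking history), B (bronchitis),
#' L (lung cancer), F (fatigue) and C (chest X-ray), with edges H->B, H->L,
#' B->F, L->F and L->C. Its conditional probabilities span several orders of
#' magnitude, which makes it a sharp probe of how dataset size limits what
#' structure learning can recover: the pinned entries are
#' `P(L=1|H=0) = 1/25000`, `P(L=1|H=1) = 1/400` and `P(B=1|H=1) = 1/20`,
#' so the joint event (H=0, L=1, C=0) occurs once in 62,500 samples. The
#' remaining entries are package defaults, chosen once: `P(H=1) = 0.2` and
#' `P(C=1|L=1) = 0.5` (these two fix the rare-event rate at exactly
#' 1/62500), `P(B=1|H=0) = 0.01`, `P(C=1|L=0) = 0.02`, and fatigue raised by
#' either disease (`0.05 / 0.10 / 0.50 / 0.75` for none / B only / L only /
#' both).
#'
#' @return a [discrete_bn] over H, B, L, F, C (categories `"0"`, `"1"`).
#' @export
fixture_five_node <- function() {
  g <- dag(c("H", "B", "L", "F", "C"),
           rbind(c("H", "B"), c("H", "L"), c("B", "F"), c("L", "F"),
                 c("L", "C")))
  b01 <- c("0", "1")
  cpts <- list(
    H = array(c(0.8, 0.2), dim = 2,
              dimnames = stats::setNames(list(b01), "H")),
    B = array(c(0.99, 0.01, 1 - 1 / 20, 1 / 20), dim = c(2, 2),
              dimnames = stats::setNames(list(b01, b01), c("B", "H"))),
    L = array(c(1 - 1 / 25000, 1 / 25000, 1 - 1 / 400, 1 / 400),
              dim = c(2, 2),
              dimnames = stats::setNames(list(b01, b01), c("L", "H"))),
    F = array(c(0.95, 0.05,   # B=0, L=0
                0.90, 0.10,   # B=1, L=0
                0.50, 0.50,   # B=0, L=1
                0.25, 0.75),  # B=1, L=1
              dim = c(2, 2, 2),
              dimnames = stats::setNames(list(b01, b01, b01),
                                         c("F", "B", "L"))),
    C = array(c(0.98, 0.02, 0.5, 0.5), dim = c(2, 2),
              dimnames = stats::setNames(list(b01, b01), c("C", "L")))
  )
  discrete_bn(g, cpts)
}

#' Twelve-node lung-cancer benchmark network
#'
#' The LUCAS-style synthetic benchmark: 12 binary variables and 12 edges
#' around the target Lung_Cancer, with five colliders and one completely
#' isolated variable, Born_an_Even_Day, fixed at probability 0.5 per state.
#' Structure: Anxiety -> Smoking <- Peer_Pressure;
#' Smoking -> Yellow_Fingers; Genetics -> Lung_Cancer <- Smoking;
#' Genetics -> Attention_Disorder; Lung_Cancer -> Coughing <- Allergy;
#' Coughing -> Fatigue <- Lung_Cancer;
#' Fatigue -> Car_Accident <- Attention_Disorder.
#'
#' The original benchmark's conditional probabilities are not bundled; the
#' default CPTs here are the package's own synthetic parameters (documented
#' below) and can be replaced wholesale through `cpts` for users who hold
#' the reference tables. Defaults: root probabilities Anxiety 0.4,
#' Peer_Pressure 0.3, Genetics 0.15, Allergy 0.2, Born_an_Even_Day 0.5;
#' child probabilities of state `"1"` per parent configuration (00/10/01/11
#' in parent sort order) — Smoking 0.2/0.6/0.5/0.85 (Anxiety,
#' Peer_Pressure), Yellow_Fingers 0.2/0.95 (Smoking),
#' Lung_Cancer 0.02/0.6/0.25/0.9 (Genetics, Smoking),
#' Attention_Disorder 0.15/0.6 (Genetics),
#' Coughing 0.1/0.7/0.85/0.95 (Allergy, Lung_Cancer),
#' Fatigue 0.15/0.55/0.75/0.9 (Coughing, Lung_Cancer),
#' Car_Accident 0.05/0.4/0.35/0.7 (Attention_Disorder, Fatigue).
#'
#' @param cpts optional named list overriding any subset of the default CPT
#'   arrays (same layout as [discrete_bn()] expects). Rows that do not sum
#'   to 1 are rejected.
#' @return a [discrete_bn] with 12 variables and 12 edges.
#' @export
fixture_lucas <- function(cpts = NULL) {
  nodes <- c("Smoking", "Yellow_Fingers", "Anxiety", "Peer_Pressure",
             "Genetics", "Attention_Disorder", "Born_an_Even_Day",
             "Car_Accident", "Fatigue", "Allergy", "Coughing",
             "Lung_Cancer")
  edges <- rbind(
    c("Anxiety", "Smoking"), c("Peer_Pressure", "Smoking"),
    c("Smoking", "Yellow_Fingers"),
    c("Genetics", "Lung_Cancer"), c("Smoking", "Lung_Cancer"),
    c("Genetics", "Attention_Disorder"),
    c("Lung_Cancer", "Coughing"), c("Allergy", "Coughing"),
    c("Coughing", "Fatigue"), c("Lung_Cancer", "Fatigue"),
    c("Fatigue", "Car_Accident"), c("Attention_Disorder", "Car_Accident"))
  g <- dag(nodes, edges)
  b01 <- c("0", "1")
  root <- function(node, p1)
    array(c(1 - p1, p1), dim = 2, dimnames = stats::setNames(list(b01), node))
  child1 <- function(node, pa, p1) {    # one parent, P(node=1 | pa=0,1)
    array(c(1 - p1[1], p1[1], 1 - p1[2], p1[2]), dim = c(2, 2),
          dimnames = stats::setNames(list(b01, b01), c(node, pa)))
  }
  child2 <- function(node, pa, p1) {    # two sorted parents, configs 00,10,01,11
    array(rbind(1 - p1, p1), dim = c(2, 2, 2),
          dimnames = stats::setNames(list(b01, b01, b01), c(node, pa)))
  }
  defaults <- list(
    Anxiety = root("Anxiety", 0.4),
    Peer_Pressure = root("Peer_Pressure", 0.3),
    Genetics = root("Genetics", 0.15),
    Allergy = root("Allergy", 0.2),
    Born_an_Even_Day = root("Born_an_Even_Day", 0.5),
    Smoking = child2("Smoking", c("Anxiety", "Peer_Pressure"),
                     c(0.2, 0.6, 0.5, 0.85)),
    Yellow_Fingers = child1("Yellow_Fingers", "Smoking", c(0.2, 0.95)),
    Lung_Cancer = child2("Lung_Cancer", c("Genetics", "Smoking"),
                         c(0.02, 0.6, 0.25, 0.9)),
    Attention_Disorder = child1("Attention_Disorder", "Genetics",
                                c(0.15, 0.6)),
    Coughing = child2("Coughing", c("Allergy", "Lung_Cancer"),
                      c(0.1, 0.7, 0.85, 0.95)),
    Fatigue = child2("Fatigue", c("Coughing", "Lung_Cancer"),
                     c(0.15, 0.55, 0.75, 0.9)),
    Car_Accident = child2("Car_Accident", c("Attention_Disorder", "Fatigue"),
                          c(0.05, 0.4, 0.35, 0.7)))
  if (!is.null(cpts)) {
    unknown <- setdiff(names(cpts), nodes)
    if (length(unknown)) stop("unknown node in cpts: ",
                              paste(unknown, collapse = ", "))
    defaults[names(cpts)] <- cpts
  }
  discrete_bn(g, defaults)
}

#' Serialize a discrete network to a text file
#'
#' JSON schema: `nodes`, `edges` (array of `[parent, child]`), `categories`
#' (per node), and `cpts` — per node the sorted parent list and the CPT
#' probabilities flattened column-major with the node's own dimension first.
#' [read_bn_model()] restores the exact model.
#'
#' @param model a [discrete_bn].
#' @param path output file path.
#' @export
write_bn_model <- function(model, path) {
  stopifnot(inherits(model, "discrete_bn"))
  g <- model$graph
  cpts <- lapply(g$nodes, function(v)
    list(parents = parents(g, v),
         prob = as.vector(model$cpts[[v]])))
  names(cpts) <- g$nodes
  jsonlite::write_json(
    list(nodes = g$nodes,
         edges = if (nrow(g$edges))
           lapply(seq_len(nrow(g$edges)), function(i) unname(g$edges[i, ]))
         else list(),
         categories = model$categories,
         cpts = cpts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a discrete network written by [write_bn_model()]
#'
#' @param path file path.
#' @return a [discrete_bn].
#' @export
read_bn_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(x$edges)) {
    if (is.matrix(x$edges)) x$edges
    else do.call(rbind, lapply(x$edges, unlist))
  } else NULL
  g <- dag(x$nodes, edges)
  cats <- lapply(x$categories, as.character)
  cpts <- list()
  for (v in x$nodes) {
    pa <- sort(as.character(x$cpts[[v]]$parents))
    dims <- unname(c(length(cats[[v]]),
                     vapply(pa, function(p) length(cats[[p]]), 0L)))
    dn <- c(list(cats[[v]]), lapply(pa, function(p) cats[[p]]))
    names(dn) <- c(v, pa)
    cpts[[v]] <- array(as.numeric(x$cpts[[v]]$prob), dim = dims, dimnames = dn)
  }
  discrete_bn(g, cpts)
}
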