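# Readers and writers: profile TSV, arc-list TSV, an extended Newick
# dialect with #H hybrid tags, and DOT export.

#' Read / write a ploidy profile TSV
#'
#' Two tab-separated columns, `label<TAB>ploidy`; lines starting with `#`
#' are comments.  The loader sorts descending (stably) and records the
#' original row order in `attr(, "source_order")`.
#'
#' @param path file path.
#' @return a [ploidy_profile()].
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no profile rows in ", path)
  labels <- character(0)
  mult <- integer(0)
  for (i in rows) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("malformed profile line ", i, " in ", path, ": expected 'label<TAB>ploidy'")
    }
    v <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(v) || v != floor(v) || v < 1) {
      stop("malformed profile line ", i, " in ", path, ": ploidy must be a positive integer")
    }
    if (parts[1] %in% labels) {
      stop("malformed profile line ", i, " in ", path, ": duplicate label ", parts[1])
    }
    labels <- c(labels, parts[1])
    mult <- c(mult, as.integer(v))
  }
  p <- ploidy_profile(mult, labels)
  attr(p, "source_order") <- labels
  p
}

#' @rdname read_profile
#' @param profile a [ploidy_profile()].
#' @export
write_profile <- function(profile, path) {
  profile <- as_profile(profile)
  writeLines(paste(profile$labels, profile$multiplicities, sep = "\t"), path)
  invisible(path)
}

#' Read / write a phylogenetic network
#'
#' Formats:
#' \describe{
#'   \item{`tsv`}{one arc per line, `tail<TAB>head`; parallel arcs are
#'     repeated lines; leaves are the out-degree-0 vertices and their
#'     vertex names are the taxon labels; `#` comments allowed.  The
#'     degenerate single-vertex network is written as the comment
#'     `# singleton <label>`.}
#'   \item{`enewick`}{extended Newick with hybrid vertices as `#Hk`
#'     tags; a bead serializes as the tag occurring twice under one
#'     parent, e.g. `((x1)#H1,#H1);`.  Tag numbering follows first
#'     appearance in a depth-first traversal with children in stored
#'     arc order.}
#'   \item{`dot`}{Graphviz export, hybrid vertices drawn filled
#'     (write only).}
#' }
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"enewick"` (and `"dot"` for writing).
#' @return `read_network`: a `phylo_network`; `write_network`: the path,
#'   invisibly.
#' @export
read_network <- function(path, format = c("tsv", "enewick")) {
  format <- match.arg(format)
  if (format == "tsv") read_network_tsv(path) else read_network_enewick(path)
}

#' @rdname read_network
#' @param network a valid [phylo_network()].
#' @export
write_network <- function(network, path, format = c("tsv", "enewick", "dot")) {
  format <- match.arg(format)
  stop_if_invalid(network)
  lines <- switch(format,
                  tsv = network_to_tsv(network),
                  enewick = network_to_enewick(network),
                  dot = network_to_dot(network))
  writeLines(lines, path)
  invisible(path)
}

network_to_tsv <- function(net) {
  if (length(net$vertices) == 1 && nrow(net$arcs) == 0) {
    return(paste0("# singleton ", unname(net$labels)))
  }
  disp <- setNames(net$vertices, net$vertices)
  disp[names(net$labels)] <- unname(net$labels)
  paste(disp[net$arcs$tail], disp[net$arcs$head], sep = "\t")
}

read_network_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  single <- grep("^# singleton ", lines, value = TRUE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) {
    if (length(single) == 1) {
      lab <- sub("^# singleton ", "", single)
      return(phylo_network(NULL, setNames(lab, "v1"), vertices = "v1"))
    }
    stop("no arcs in ", path)
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop("malformed arc line ", which(keep)[bad[1]], " in ", path)
  }
  arcs <- data.frame(tail = vapply(parts, `[`, "", 1),
                     head = vapply(parts, `[`, "", 2))
  vertices <- unique(c(arcs$tail, arcs$head))
  is_tail <- vertices %in% arcs$tail
  leaves <- vertices[!is_tail]
  net <- phylo_network(arcs, setNames(leaves, leaves), vertices = vertices)
  bad <- validate_network(net)
  if (length(bad)) stop("invalid network in ", path, ": ", paste(bad, collapse = "; "))
  net
}

network_to_enewick <- function(net) {
  if (length(net$vertices) == 1 && nrow(net$arcs) == 0) {
    return(paste0(unname(net$labels), ";"))
  }
  root <- pn_root(net)
  ind <- pn_indeg(net)
  hyb_no <- integer(0)
  next_h <- 1L
  arcs <- net$arcs
  labels <- net$labels
  render <- function(v) {
    if (ind[v] >= 2L) {
      if (!is.null(hyb_no[v]) && !is.na(hyb_no[v])) {
        return(paste0("#H", hyb_no[v]))
      }
      hyb_no[v] <<- next_h
      next_h <<- next_h + 1L
      kid <- arcs$head[arcs$tail == v]
      return(paste0("(", render(kid), ")#H", hyb_no[v]))
    }
    kids <- arcs$head[arcs$tail == v]
    if (!length(kids)) return(unname(labels[v]))
    paste0("(", paste(vapply(kids, render, ""), collapse = ","), ")")
  }
  hyb_no <- setNames(rep(NA_integer_, length(net$vertices)), net$vertices)
  paste0(render(root), ";")
}

read_network_enewick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\s", "", txt)
  txt <- sub(";$", "", txt)
  if (!nchar(txt)) stop("empty extended-Newick string in ", path)
  env <- new.env()
  env$arcs_t <- character(0)
  env$arcs_h <- character(0)
  env$labels <- character(0)
  env$hyb <- character(0)     # tag -> vertex id
  env$hyb_def <- character(0) # tags whose children were already given
  env$k <- 0L
  fresh <- function() {
    env$k <- env$k + 1L
    paste0("v", env$k)
  }
  pos <- 1L
  n <- nchar(txt)
  peek <- function() if (pos > n) "" else substr(txt, pos, pos)
  parse_node <- function() {
    kids <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids <- c(kids, parse_node())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("parse error at position ", pos, " in extended Newick")
      }
    }
    start <- pos
    while (pos <= n && !(peek() %in% c("(", ")", ",", ";"))) pos <<- pos + 1L
    tail_txt <- substr(txt, start, pos - 1L)
    name <- sub("#H[0-9]+$", "", tail_txt)
    tag <- regmatches(tail_txt, regexpr("#H[0-9]+$", tail_txt))
    if (length(tag) && nchar(tag)) {
      if (is.na(env$hyb[tag])) env$hyb[tag] <- fresh()
      v <- unname(env$hyb[tag])
      if (length(kids)) {
        if (tag %in% env$hyb_def) {
          stop("hybrid tag ", tag, " defines children twice")
        }
        env$hyb_def <- c(env$hyb_def, tag)
      }
    } else {
      v <- fresh()
      if (!length(kids)) {
        if (!nchar(name)) stop("unlabelled leaf in extended Newick")
        env$labels[v] <- name
      }
    }
    for (kid in kids) {
      env$arcs_t <- c(env$arcs_t, v)
      env$arcs_h <- c(env$arcs_h, kid)
    }
    v
  }
  env$hyb <- setNames(rep(NA_character_, 0), character(0))
  root <- parse_node()
  if (pos <= n) stop("trailing characters in extended Newick")
  if (!length(env$arcs_t)) {
    lab <- env$labels[root]
    return(phylo_network(NULL, setNames(unname(lab), "v1"), vertices = "v1"))
  }
  net <- phylo_network(data.frame(tail = env$arcs_t, head = env$arcs_h),
                       env$labels)
  bad <- validate_network(net)
  if (length(bad)) stop("invalid network in ", path, ": ", paste(bad, collapse = "; "))
  pn_renumber(net)
}

network_to_dot <- function(net) {
  ind <- pn_indeg(net)
  lines <- c("digraph network {", "  rankdir=TB;")
  for (v in net$vertices) {
    lab <- if (v %in% names(net$labels)) unname(net$labels[v]) else ""
    style <- if (!is.na(ind[v]) && ind[v] >= 2L) {
      " [shape=circle, style=filled, fillcolor=black, width=0.15, label=\"\"]"
    } else if (nchar(lab)) {
      paste0(" [shape=none, label=\"", lab, "\"]")
    } else {
      " [shape=point]"
    }
    lines <- c(lines, paste0("  \"", v, "\"", style, ";"))
  }
  for (i in seq_len(nrow(net$arcs))) {
    lines <- c(lines, paste0("  \"", net$arcs$tail[i], "\" -> \"",
                             net$arcs$head[i], "\";"))
  }
  c(lines, "}")
}
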