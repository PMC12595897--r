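#' Heterogeneous drug-target network
#'
#' Container for the six typed binary adjacency blocks linking drugs (D),
#' targets (T), diseases (I) and side-effects (S). All blocks are dense 0/1
#' matrices; `A_DD` and `A_TT` are symmetric with zero diagonal.
#'
#' @param drug_ids,target_ids,disease_ids,side_effect_ids character vectors of
#'   node identifiers; their order fixes row/column order of all blocks.
#' @param A_DD,A_DT,A_DI,A_DS,A_TT,A_TI binary adjacency matrices with
#'   dimensions matching the id vectors.
#' @return An object of class `hetero_network`.
#' @export
hetero_network <- function(drug_ids, target_ids, disease_ids, side_effect_ids,
                           A_DD, A_DT, A_DI, A_DS, A_TT, A_TI) {
  net <- structure(list(
    drug_ids = as.character(drug_ids),
    target_ids = as.character(target_ids),
    disease_ids = as.character(disease_ids),
    side_effect_ids = as.character(side_effect_ids),
    A_DD = as_binary_matrix(A_DD), A_DT = as_binary_matrix(A_DT),
    A_DI = as_binary_matrix(A_DI), A_DS = as_binary_matrix(A_DS),
    A_TT = as_binary_matrix(A_TT), A_TI = as_binary_matrix(A_TI)
  ), class = "hetero_network")
  validate_hetero_network(net)
  net
}

as_binary_matrix <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  A
}

validate_hetero_network <- function(net) {
  Nd <- length(net$drug_ids); Nt <- length(net$target_ids)
  Ni <- length(net$disease_ids); Ns <- length(net$side_effect_ids)
  if (Nd == 0L) stop("hetero_network: drug id list is empty")
  if (Nt == 0L) stop("hetero_network: target id list is empty")
  dims <- list(A_DD = c(Nd, Nd), A_DT = c(Nd, Nt), A_DI = c(Nd, Ni),
               A_DS = c(Nd, Ns), A_TT = c(Nt, Nt), A_TI = c(Nt, Ni))
  for (nm in names(dims)) {
    A <- net[[nm]]
    if (!identical(dim(A), as.integer(dims[[nm]])) &&
        !identical(dim(A), dims[[nm]]))
      stop(sprintf("hetero_network: %s has dimensions %dx%d, expected %dx%d",
                   nm, nrow(A), ncol(A), dims[[nm]][1], dims[[nm]][2]))
    if (length(A) && !all(A %in% c(0, 1)))
      stop(sprintf("hetero_network: %s has entries outside {0,1}", nm))
  }
  for (nm in c("A_DD", "A_TT")) {
    A <- net[[nm]]
    if (length(A)) {
      if (!isTRUE(all.equal(A, t(A)))) stop(sprintf("%s must be symmetric", nm))
      if (any(diag(A) != 0)) stop(sprintf("%s must have zero diagonal", nm))
    }
  }
  invisible(net)
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("Heterogeneous drug-target network\n")
  cat(sprintf("  drugs: %d  targets: %d  diseases: %d  side-effects: %d\n",
              length(x$drug_ids), length(x$target_ids),
              length(x$disease_ids), length(x$side_effect_ids)))
  for (nm in c("A_DD", "A_DT", "A_DI", "A_DS", "A_TT", "A_TI"))
    cat(sprintf("  %s: %d edges\n", nm,
                if (nm %in% c("A_DD", "A_TT")) sum(x[[nm]]) / 2 else sum(x[[nm]])))
  invisible(x)
}

# Build a binary adjacency block from an edge table. Unknown endpoints are a
# hard error naming the offending edge; duplicates collapse to 1; self-loops
# are dropped for the symmetric (unipartite) relations.
adjacency_from_edges <- function(edges, row_ids, col_ids, symmetric = FALSE,
                                 relation = "edge") {
  A <- matrix(0, length(row_ids), length(col_ids))
  if (is.null(edges) || nrow(edges) == 0L) return(A)
  i <- match(as.character(edges[[1]]), row_ids)
  j <- match(as.character(edges[[2]]), col_ids)
  if (symmetric) {
    # either endpoint may appear in either column of an undirected edge list
    i2 <- match(as.character(edges[[1]]), col_ids)
    j2 <- match(as.character(edges[[2]]), row_ids)
    i[is.na(i)] <- j2[is.na(i)]
    j[is.na(j)] <- i2[is.na(j)]
  }
  bad <- which(is.na(i) | is.na(j))
  if (length(bad))
    stop(sprintf("%s: unknown node id in edge (%s, %s)", relation,
                 edges[[1]][bad[1]], edges[[2]][bad[1]]))
  keep <- !(symmetric & i == j)
  A[cbind(i[keep], j[keep])] <- 1
  if (symmetric) {
    A <- pmax(A, t(A))
    diag(A) <- 0
  }
  A
}

#' Read a heterogeneous network from node lists and edge tables
#'
#' Node lists are plain text files with one identifier per line (order
#' defining); edge lists are headered two-column TSV files
#' (`source_id<TAB>target_id`). Drug-drug and target-target edges are treated
#' as undirected and closed symmetrically; duplicate edges collapse to a
#' single 1. Expected file names under `dir`: `drugs.txt`, `targets.txt`,
#' `diseases.txt`, `side_effects.txt`, `drug_drug.tsv`, `drug_target.tsv`,
#' `drug_disease.tsv`, `drug_side_effect.tsv`, `target_target.tsv`,
#' `target_disease.tsv`. Missing edge files yield empty blocks.
#'
#' @param dir directory containing the files above.
#' @return A [hetero_network()].
#' @export
read_hetero_network <- function(dir) {
  read_ids <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing node list: ", p)
    readLines(p, warn = FALSE)
  }
  read_edges <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p, colClasses = "character")
  }
  drugs <- read_ids("drugs.txt"); targets <- read_ids("targets.txt")
  diseases <- read_ids("diseases.txt"); sides <- read_ids("side_effects.txt")
  hetero_network(
    drugs, targets, diseases, sides,
    A_DD = adjacency_from_edges(read_edges("drug_drug.tsv"), drugs, drugs,
                                symmetric = TRUE, relation = "drug_drug"),
    A_DT = adjacency_from_edges(read_edges("drug_target.tsv"), drugs, targets,
                                relation = "drug_target"),
    A_DI = adjacency_from_edges(read_edges("drug_disease.tsv"), drugs, diseases,
                                relation = "drug_disease"),
    A_DS = adjacency_from_edges(read_edges("drug_side_effect.tsv"), drugs, sides,
                                relation = "drug_side_effect"),
    A_TT = adjacency_from_edges(read_edges("target_target.tsv"), targets, targets,
                                symmetric = TRUE, relation = "target_target"),
    A_TI = adjacency_from_edges(read_edges("target_disease.tsv"), targets, diseases,
                                relation = "target_disease")
  )
}

#' Write a heterogeneous network as node lists and edge tables
#'
#' Inverse of [read_hetero_network()]: writes one id-per-line node lists and
#' headered TSV edge lists (undirected relations written once per edge,
#' upper triangle).
#'
#' @param net a [hetero_network()].
#' @param dir output directory (created if absent).
#' @export
write_hetero_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(net$drug_ids, file.path(dir, "drugs.txt"))
  writeLines(net$target_ids, file.path(dir, "targets.txt"))
  writeLines(net$disease_ids, file.path(dir, "diseases.txt"))
  writeLines(net$side_effect_ids, file.path(dir, "side_effects.txt"))
  wr <- function(A, rows, cols, f, upper = FALSE) {
    idx <- which(A == 1, arr.ind = TRUE)
    if (upper) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    df <- data.frame(source_id = rows[idx[, 1]], target_id = cols[idx[, 2]])
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(net$A_DD, net$drug_ids, net$drug_ids, "drug_drug.tsv", upper = TRUE)
  wr(net$A_DT, net$drug_ids, net$target_ids, "drug_target.tsv")
  wr(net$A_DI, net$drug_ids, net$disease_ids, "drug_disease.tsv")
  wr(net$A_DS, net$drug_ids, net$side_effect_ids, "drug_side_effect.tsv")
  wr(net$A_TT, net$target_ids, net$target_ids, "target_target.tsv", upper = TRUE)
  wr(net$A_TI, net$target_ids, net$disease_ids, "target_disease.tsv")
  invisible(dir)
}

#' Assemble a block heterogeneous matrix over drugs and targets
#'
#' Stacks a drug-drug block, a target-target block and a drug-target block
#' into the (N_d + N_t) square matrix
#' \deqn{\begin{pmatrix} B_D & Y \\ Y^\top & B_T \end{pmatrix}}
#' used both for the interaction network (drug/target adjacency + fused DTI
#' matrix) and the similarity network (fused similarities + fused DTI
#' matrix). Drugs occupy the first `N_d` rows, targets the rest.
#'
#' @param net a [hetero_network()] providing dimensions and node ids.
#' @param Y_DTI binary `N_d x N_t` drug-target block.
#' @param drug_block symmetric `N_d x N_d` matrix.
#' @param target_block symmetric `N_t x N_t` matrix.
#' @param kind `"interaction"` or `"similarity"` (bookkeeping label).
#' @return An object of class `block_hetero` with elements `matrix`, `kind`
#'   and `split_index` (= `N_d`).
#' @export
assemble_block <- function(net, Y_DTI, drug_block, target_block,
                           kind = c("interaction", "similarity")) {
  kind <- match.arg(kind)
  Nd <- length(net$drug_ids); Nt <- length(net$target_ids)
  Y_DTI <- as.matrix(Y_DTI)
  drug_block <- as.matrix(drug_block); target_block <- as.matrix(target_block)
  if (!identical(dim(Y_DTI), c(Nd, Nt)) && !all(dim(Y_DTI) == c(Nd, Nt)))
    stop("assemble_block: Y_DTI must be N_d x N_t")
  if (!all(dim(drug_block) == c(Nd, Nd)))
    stop("assemble_block: drug_block must be N_d x N_d")
  if (!all(dim(target_block) == c(Nt, Nt)))
    stop("assemble_block: target_block must be N_t x N_t")
  M <- rbind(cbind(drug_block, Y_DTI), cbind(t(Y_DTI), target_block))
  ids <- c(net$drug_ids, net$target_ids)
  dimnames(M) <- list(ids, ids)
  structure(list(matrix = M, kind = kind, split_index = Nd),
            class = "block_hetero")
}

#' @export
print.block_hetero <- function(x, ...) {
  cat(sprintf("Block heterogeneous matrix (%s): %d x %d, split at %d\n",
              x$kind, nrow(x$matrix), ncol(x$matrix), x$split_index))
  invisible(x)
}

block_matrix <- function(x) if (inherits(x, "block_hetero")) x$matrix else as.matrix(x)

#' Write / read a matrix in Matrix Market format
#'
#' Sparse coordinate MTX, suitable for adjacency and mask matrices.
#' @param A matrix (dense or `Matrix` sparse).
#' @param path file path.
#' @export
write_mtx <- function(A, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(as.matrix(A)),
                                          "generalMatrix"), "CsparseMatrix"),
                  path)
  invisible(path)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  storage.mode(m) <- "double"
  m
}
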