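test_that("edge detection keeps perfect correlations and controls the null", {
    set.seed(41)
    x <- matrix(rnorm(50 * 6), 50, 6)
    x <- cbind(x, x[, 1])                      # duplicated node, rho = 1
    colnames(x) <- c(paste0("v", 1:6), "dup")
    e <- edgeFDR(x, nPerm = 5000, seed = 1)
    expect_true(any((e$from == "v1" & e$to == "dup") |
                    (e$from == "dup" & e$to == "v1")))
    ## independent noise: essentially nothing survives the 1 percent FDR
    set.seed(42)
    xn <- matrix(rnorm(50 * 20), 50, 20)
    en <- edgeFDR(xn, nPerm = 2000, seed = 2)
    expect_lte(nrow(en) / choose(20, 2), 0.01)
})

test_that("constant nodes are excluded and small inputs rejected", {
    set.seed(43)
    x <- cbind(matrix(rnorm(30 * 4), 30, 4), flat = rep(1, 30))
    colnames(x)[1:4] <- paste0("v", 1:4)
    expect_message(e <- edgeFDR(x, nPerm = 500, seed = 1), "flat")
    expect_false("flat" %in% c(e$from, e$to))
    expect_error(edgeFDR(x[1:5, ], nPerm = 500), "at least 10 samples")
})

test_that("edge sets are invariant to node order and symmetric", {
    set.seed(44)
    f <- rnorm(40)
    x <- sapply(1:8, function(i) f + rnorm(40, 0, 0.5))
    colnames(x) <- paste0("v", 1:8)
    key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
    e1 <- edgeFDR(x, nPerm = 2000, seed = 5)
    e2 <- edgeFDR(x[, sample(8)], nPerm = 2000, seed = 5)
    expect_identical(key(e1), key(e2))
})

test_that("two disconnected cliques come back as exactly two modules", {
    mk_clique <- function(nodes, rho) {
        p <- t(combn(nodes, 2))
        data.frame(from = p[, 1], to = p[, 2], rho = rho)
    }
    edges <- rbind(mk_clique(paste0("a", 1:5), 0.9),
                   mk_clique(paste0("b", 1:4), 0.8))
    net <- detectModules(edges, nPerm = 99, seed = 1)
    mods <- networkModules(net)
    expect_length(mods, 2)
    expect_setequal(mods[[which(lengths(mods) == 5)]], paste0("a", 1:5))
    ## empty input: empty module list, not an error
    empty <- detectModules(edges[0, ], nPerm = 99, seed = 1)
    expect_length(networkModules(empty), 0)
})

test_that("a planted correlated block is recovered as one module", {
    set.seed(45)
    nsamp <- 50
    f <- rnorm(nsamp)
    x <- cbind(sapply(1:12, function(i) f + rnorm(nsamp, 0, 0.45)),
               matrix(rnorm(nsamp * 30), nsamp, 30))
    colnames(x) <- sprintf("v%02d", 1:42)
    ## all 66 within-block pairs should pass the gate at this strength
    net <- coexpressionNetwork(x, nPermEdges = 10000, nPermModules = 99,
                               seed = 6)
    mods <- networkModules(net)
    jac <- vapply(mods, function(m)
        length(intersect(m, colnames(x)[1:12])) /
        length(union(m, colnames(x)[1:12])), numeric(1))
    expect_gte(max(jac), 0.8)
})

test_that("a star center is a hub while a clique has none", {
    star <- data.frame(from = "hub", to = paste0("s", 1:10), rho = 0.9)
    attr(star, "nullEdgeRate") <- 0.005
    attr(star, "nSamples") <- 40
    net <- identifyHubs(detectModules(star, nPerm = 49, seed = 1))
    expect_identical(hubGenes(net), "hub")
    p <- t(combn(paste0("c", 1:8), 2))
    clique <- data.frame(from = p[, 1], to = p[, 2], rho = 0.9)
    attr(clique, "nullEdgeRate") <- 0.005
    attr(clique, "nSamples") <- 40
    netc <- identifyHubs(detectModules(clique, nPerm = 49, seed = 1))
    expect_length(hubGenes(netc), 0)
})

test_that("module and hub accessors expose a consistent object", {
    star <- data.frame(from = "hub", to = paste0("s", 1:6), rho = 0.9)
    attr(star, "nullEdgeRate") <- 0.01
    attr(star, "nSamples") <- 30
    net <- identifyHubs(detectModules(star, nPerm = 49, seed = 2))
    expect_s4_class(net, "CoexpressionNetwork")
    expect_true(all(hubGenes(net) %in% unlist(networkModules(net))))
    expect_length(moduleSignificance(net), length(networkModules(net)))
    expect_true(validObject(net))
})
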