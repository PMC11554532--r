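test_that("the 3-residual-block builder has the promised structure", {
  g <- build_three_residual_model(4)
  kinds <- vapply(g$layers, function(l) l$kind, "")
  expect_identical(sum(kinds == "add"), 3L)
  expect_identical(sum(kinds == "batchnorm"), 0L)
  rep <- infer_shapes(g)
  expect_identical(rep$gap_width, 2048L)
  expect_lt(rep$total_params, 11.7e6)
  # head: gap -> fc(num_classes) -> softmax
  fc <- g$layers[[names(kinds)[kinds == "fc"]]]
  expect_identical(fc$depth, 4L)
  expect_identical(kinds[[length(kinds)]], "softmax")
})

test_that("the 4-residual-block builder has the promised structure", {
  g <- build_four_residual_model(4)
  kinds <- vapply(g$layers, function(l) l$kind, "")
  expect_identical(sum(kinds == "add"), 4L)
  expect_identical(sum(kinds == "batchnorm"), 4L)
  rep <- infer_shapes(g)
  expect_identical(rep$gap_width, 2048L)
  expect_lt(rep$total_params, 23.5e6)
})

test_that("only the classifier head depends on the class count", {
  g4 <- build_three_residual_model(4)
  g2 <- build_three_residual_model(2)
  k4 <- vapply(g4$layers, function(l) l$kind, "")
  expect_identical(vapply(g2$layers, function(l) l$kind, ""), k4)
  fc4 <- g4$layers[[names(k4)[k4 == "fc"]]]
  fc2 <- g2$layers[[names(k4)[k4 == "fc"]]]
  expect_identical(c(fc4$depth, fc2$depth), c(4L, 2L))
  body4 <- g4$layers[k4 != "fc"]
  body2 <- g2$layers[k4 != "fc"]
  expect_identical(lapply(body2, unclass), lapply(body4, unclass))
})

test_that("too-small input images are rejected, naming the dimension", {
  err <- expect_error(build_three_residual_model(4, c(16, 16, 3)),
                      class = "config_error")
  expect_match(conditionMessage(err), "dimension 1 is 16")
  expect_error(build_four_residual_model(4, c(224, 20, 3)),
               class = "config_error")
})

test_that("shape inference matches hand arithmetic on single layers", {
  # conv: 3x3x3 -> 32, stride 2, same padding on 224x224x3
  g <- model_graph(
    list(layer_spec("input", "input"),
         layer_spec("c", "conv", depth = 32, kernel = 3, stride = 2),
         layer_spec("gap", "gap"),
         layer_spec("fc", "fc", depth = 4),
         layer_spec("sm", "softmax")),
    list(c("input", "c"), c("c", "gap"), c("gap", "fc"), c("fc", "sm")),
    4, c(224, 224, 3))
  rep <- infer_shapes(g)
  expect_identical(rep$shapes$c, c(112L, 112L, 32L))
  expect_identical(unname(rep$params["c"]), 3 * 3 * 3 * 32 + 32)
  # fc from a 2048-wide gap: 2048 * 4 + 4
  g2 <- model_graph(
    list(layer_spec("input", "input"),
         layer_spec("c", "conv", depth = 2048, kernel = 1, stride = 1),
         layer_spec("gap", "gap"),
         layer_spec("fc", "fc", depth = 4),
         layer_spec("sm", "softmax")),
    list(c("input", "c"), c("c", "gap"), c("gap", "fc"), c("fc", "sm")),
    4, c(8, 8, 3))
  expect_identical(unname(infer_shapes(g2)$params["fc"]), 2048 * 4 + 4)
})

test_that("mismatched shortcut shapes raise a structural error naming the layer", {
  g <- list(
    layers = list(layer_spec("input", "input"),
                  layer_spec("c1", "conv", depth = 8, kernel = 3, stride = 2),
                  layer_spec("bad_add", "add"),
                  layer_spec("gap", "gap"),
                  layer_spec("fc", "fc", depth = 2),
                  layer_spec("sm", "softmax")),
    edges = list(c("input", "c1"), c("c1", "bad_add"), c("input", "bad_add"),
                 c("bad_add", "gap"), c("gap", "fc"), c("fc", "sm")))
  graph <- model_graph(g$layers, g$edges, 2, c(32, 32, 3))
  err <- expect_error(infer_shapes(graph), class = "graph_error")
  expect_match(conditionMessage(err), "bad_add")
})

test_that("graph validation enforces degrees, acyclicity and softmax sinks", {
  mk <- function(edges) model_graph(
    list(layer_spec("input", "input"),
         layer_spec("r", "relu"),
         layer_spec("sm", "softmax")),
    edges, 2, c(8, 8, 1))
  expect_error(mk(list(c("input", "r"), c("r", "sm"), c("input", "sm"))),
               class = "graph_error")  # softmax with in-degree 2
  expect_silent(mk(list(c("input", "r"), c("r", "sm"))))
  # terminal layer that is not softmax
  expect_error(model_graph(
    list(layer_spec("input", "input"), layer_spec("r", "relu")),
    list(c("input", "r")), 2, c(8, 8, 1)), class = "graph_error")
})

test_that("serialization round-trips and rejects malformed documents", {
  g <- build_three_residual_model(4)
  js <- serialize_graph(g)
  g2 <- deserialize_graph(js)
  expect_identical(lapply(g2$layers, unclass), lapply(g$layers, unclass))
  expect_identical(g2$edges, g$edges)
  expect_identical(g2$input_shape, g$input_shape)

  doc <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  doc$edges <- NULL
  err <- expect_error(
    deserialize_graph(jsonlite::toJSON(doc, auto_unbox = TRUE)),
    class = "parse_error")
  expect_match(conditionMessage(err), "edges")

  two <- '{"input_shape": [8, 8, 1], "num_classes": 2,
           "layers": [{"name": "input", "kind": "input"},
                      {"name": "sm", "kind": "softmax"}],
           "edges": [["input", "sm"]]}'
  expect_length(deserialize_graph(two)$layers, 2)
})

test_that("forward evaluation produces a proper softmax distribution", {
  g <- micro_cnn_graph(4, c(32, 32, 3))
  net <- init_network(g, seed = 7)
  imgs <- generate_plane_images(image_set_spec(per_class = 2, size = 32,
                                               seed = 1))
  A <- planefusion:::images_to_activation(imgs$images, c(32, 32, 3))
  p <- planefusion:::network_predict(net, A, length(imgs$images))
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-6)
})

test_that("consecutive relu layers change no forward output", {
  base <- list(layer_spec("input", "input"),
               layer_spec("c", "conv", depth = 4, kernel = 3, stride = 1),
               layer_spec("r1", "relu"),
               layer_spec("gap", "gap"),
               layer_spec("fc", "fc", depth = 2),
               layer_spec("sm", "softmax"))
  g1 <- model_graph(base,
    list(c("input", "c"), c("c", "r1"), c("r1", "gap"), c("gap", "fc"),
         c("fc", "sm")), 2, c(8, 8, 1))
  g2 <- model_graph(append(base, list(layer_spec("r2", "relu")), after = 3),
    list(c("input", "c"), c("c", "r1"), c("r1", "r2"), c("r2", "gap"),
         c("gap", "fc"), c("fc", "sm")), 2, c(8, 8, 1))
  n1 <- init_network(g1, seed = 5)
  n2 <- init_network(g2, seed = 5)
  n2$params <- n1$params  # identical weights, extra relu
  A <- matrix(stats::rnorm(64), 64, 1)
  p1 <- planefusion:::network_predict(n1, A, 1)
  p2 <- planefusion:::network_predict(n2, A, 1)
  expect_equal(p1, p2, tolerance = 1e-12)
})
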