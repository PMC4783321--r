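Package: kissrd
Title: Exponential Time Differencing Simulation of the Extended
    Kierstead-Slobodkin Reaction-Diffusion Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the extended nonlinear Kierstead-Slobodkin (KiSS)
    critical-patch reaction-diffusion model u_t = D Laplacian(u) + tau u^alpha
    in one and two spatial dimensions. Space is discretized by fourth-order
    central differences (Dirichlet) or a Fourier spectral method (periodic);
    time integration uses the fourth-order exponential time differencing
    Runge-Kutta scheme (ETDRK4) with numerically stable contour-integral
    evaluation of the phi-function weights, alongside exponential
    Adams-Bashforth multistep comparators of orders four to six. Includes the
    analytic series solution of the linear model, the critical patch size
    criterion pi*sqrt(D/tau), heat-kernel and error-function solutions of the
    diffusion-only limit, linear stability analysis of ETDRK4 (exact bivariate
    expansion of the amplification factor and stability-region boundary
    tracing), and convergence and patch-size experiment harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
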