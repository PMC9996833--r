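# Built-in Gaussian basis set library (spherical harmonics; s/p/d shells).
# Shells are stored split (no sp supershells); coefficients refer to
# normalized primitives, as published.

.sto3g_1s_coef <- c(0.1543289673, 0.5353281423, 0.4446345422)
.sto3g_2s_coef <- c(-0.09996722919, 0.3995128261, 0.7001154689)
.sto3g_2p_coef <- c(0.1559162750, 0.6076837186, 0.3919573931)

.basis_library <- list(
  "sto-3g" = list(
    H = list(list(l = 0L, exp = c(3.425250914, 0.6239137298, 0.1688554040),
                  coef = .sto3g_1s_coef)),
    Li = list(
      list(l = 0L, exp = c(16.11957475, 2.936200663, 0.7946504870),
           coef = .sto3g_1s_coef),
      list(l = 0L, exp = c(0.6362897469, 0.1478600533, 0.04808867840),
           coef = .sto3g_2s_coef),
      list(l = 1L, exp = c(0.6362897469, 0.1478600533, 0.04808867840),
           coef = .sto3g_2p_coef)),
    C = list(
      list(l = 0L, exp = c(71.61683735, 13.04509632, 3.530512160),
           coef = .sto3g_1s_coef),
      list(l = 0L, exp = c(2.941249355, 0.6834830964, 0.2222899159),
           coef = .sto3g_2s_coef),
      list(l = 1L, exp = c(2.941249355, 0.6834830964, 0.2222899159),
           coef = .sto3g_2p_coef)),
    N = list(
      list(l = 0L, exp = c(99.10616896, 18.05231239, 4.885660238),
           coef = .sto3g_1s_coef),
      list(l = 0L, exp = c(3.780455879, 0.8784966449, 0.2857143744),
           coef = .sto3g_2s_coef),
      list(l = 1L, exp = c(3.780455879, 0.8784966449, 0.2857143744),
           coef = .sto3g_2p_coef)),
    O = list(
      list(l = 0L, exp = c(130.7093214, 23.80886605, 6.443608313),
           coef = .sto3g_1s_coef),
      list(l = 0L, exp = c(5.033151319, 1.169596125, 0.3803889600),
           coef = .sto3g_2s_coef),
      list(l = 1L, exp = c(5.033151319, 1.169596125, 0.3803889600),
           coef = .sto3g_2p_coef))
  ),
  "6-31g" = list(
    H = list(
      list(l = 0L, exp = c(18.73113700, 2.825393700, 0.6401217000),
           coef = c(0.03349460434, 0.2347269535, 0.8137573261)),
      list(l = 0L, exp = 0.1612777588, coef = 1.0)),
    C = list(
      list(l = 0L,
           exp = c(3047.524880, 457.3695180, 103.9486850, 29.21015530,
                   9.286662960, 3.163926960),
           coef = c(0.001834737132, 0.01403732281, 0.06884262226,
                    0.2321844432, 0.4679413484, 0.3623119853)),
      list(l = 0L, exp = c(7.868272350, 1.881288540, 0.5442492580),
           coef = c(-0.1193324198, -0.1608541517, 1.143456438)),
      list(l = 1L, exp = c(7.868272350, 1.881288540, 0.5442492580),
           coef = c(0.06899906659, 0.3164239610, 0.7443082909)),
      list(l = 0L, exp = 0.1687144782, coef = 1.0),
      list(l = 1L, exp = 0.1687144782, coef = 1.0)),
    O = list(
      list(l = 0L,
           exp = c(5484.671660, 825.2349460, 188.0469580, 52.96450000,
                   16.89757040, 5.799635340),
           coef = c(0.001831074430, 0.01395017220, 0.06844507810,
                    0.2327143360, 0.4701928980, 0.3585208530)),
      list(l = 0L, exp = c(15.53961625, 3.599933586, 1.013761750),
           coef = c(-0.1107775495, -0.1480262627, 1.130767015)),
      list(l = 1L, exp = c(15.53961625, 3.599933586, 1.013761750),
           coef = c(0.07087426823, 0.3397528391, 0.7271585773)),
      list(l = 0L, exp = 0.2700058226, coef = 1.0),
      list(l = 1L, exp = 0.2700058226, coef = 1.0))
  ),
  "cc-pvdz" = list(
    H = list(
      list(l = 0L, exp = c(13.01000000, 1.962000000, 0.4446000000),
           coef = c(0.01968500, 0.1379770, 0.4781480)),
      list(l = 0L, exp = 0.1220000000, coef = 1.0),
      list(l = 1L, exp = 0.7270000000, coef = 1.0))
  )
)

# 6-31g(d): 6-31g plus a single d polarization shell on heavy atoms
.basis_library[["6-31g(d)"]] <- local({
  b <- .basis_library[["6-31g"]]
  for (el in c("C", "O"))
    b[[el]] <- c(b[[el]], list(list(l = 2L, exp = 0.8, coef = 1.0)))
  b
})

# Published contracted shell compositions (counts of s, p, d, f, g shells)
# for basis-function counting when full exponent data is not bundled.
.basis_compositions <- list(
  "cc-pvdz" = list(
    H = c(2L, 1L), He = c(2L, 1L),
    B = c(3L, 2L, 1L), C = c(3L, 2L, 1L), N = c(3L, 2L, 1L),
    O = c(3L, 2L, 1L), F = c(3L, 2L, 1L), Ne = c(3L, 2L, 1L),
    Fe = c(8L, 6L, 4L, 2L, 1L)
  )
)

# number of spherical functions for a shell of angular momentum l
.n_sph <- function(l) 2L * l + 1L
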