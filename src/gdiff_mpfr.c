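/* Extended-precision evaluation of the endpoint difference
 *   D = G(yL, h) - G(y0, h)
 * of the closed-form primitive of the integrated sphere-rod potential,
 * for either sign of u = h^2 - a^2 (u != 0).  Near tangency (h ~ a) the
 * individual terms diverge like u^-8 while D stays finite, so double
 * precision loses all significant digits; this kernel evaluates the sum
 * at a caller-chosen MPFR precision.
 *
 * Branches:
 *   u > 0: arctan tail, paired as atan((yL-y0) sqrt(u) / (u + y0 yL))
 *          when both endpoints lie on the same side of the projection.
 *   u < 0: real logarithmic tail, log1p(-2 v (yL - y0) / ((v+yL)(v-y0)))
 *          with v = sqrt(-u); valid for every non-overlapping rod.
 */

#include <R.h>
#include <Rinternals.h>
#include <mpfr.h>

/* accumulate the rational (non-arctan) part of G at endpoint y into acc:
 * acc += sig6 * ( 8 a6 y / (15 u s^8)
 *               - c2n y / (35 u^2 s^7)          c2n = 4(4 a6 - 9 a4 h2)
 *               + c3n y / (105 u^3 s^6)         c3n = 11a6 - 9a4 h2 + 63 a2 h4
 *               + N y ( 1/(1050 u^4 s^5) + 3/(2800 u^5 s^4)
 *                     + 1/(800 u^6 s^3) + 1/(640 u^7 s^2)
 *                     + 3/(1280 u^8 s) ) )
 *        - ( y / (4 u s^2) + 3 y / (8 u^2 s) )
 * with s = u + y^2, each term multiplied by 'sgn' (+1 for yL, -1 for y0).
 */
static void acc_rational(mpfr_t acc, mpfr_t y, mpfr_t u,
                         mpfr_t a6c, mpfr_t c2n, mpfr_t c3n, mpfr_t N,
                         mpfr_t sig6, int sgn, mpfr_prec_t prec)
{
    mpfr_t s, t, term, upow, spow;
    mpfr_inits2(prec, s, t, term, upow, spow, (mpfr_ptr) 0);

    /* s = u + y^2 */
    mpfr_sqr(s, y, MPFR_RNDN);
    mpfr_add(s, s, u, MPFR_RNDN);

    /* helper macro: term = coef_num * y / (den_const * u^pu * s^ps) */
#define RAT_TERM(coef, den_const, pu, ps, repulsive)            \
    do {                                                        \
        mpfr_pow_ui(upow, u, (pu), MPFR_RNDN);                  \
        mpfr_pow_ui(spow, s, (ps), MPFR_RNDN);                  \
        mpfr_mul(term, (coef), y, MPFR_RNDN);                   \
        mpfr_div(term, term, upow, MPFR_RNDN);                  \
        mpfr_div(term, term, spow, MPFR_RNDN);                  \
        mpfr_div_ui(term, term, (den_const), MPFR_RNDN);        \
        if (repulsive) mpfr_mul(term, term, sig6, MPFR_RNDN);   \
        if (sgn < 0) mpfr_neg(term, term, MPFR_RNDN);           \
        mpfr_add(acc, acc, term, MPFR_RNDN);                    \
    } while (0)

    /* 8 a6 y / (15 u s^8) : coefficient 8*a6 with /15 */
    mpfr_mul_ui(t, a6c, 8, MPFR_RNDN);
    RAT_TERM(t, 15, 1, 8, 1);
    /* - c2n y / (35 u^2 s^7) */
    mpfr_neg(t, c2n, MPFR_RNDN);
    RAT_TERM(t, 35, 2, 7, 1);
    /* + c3n y / (105 u^3 s^6) */
    mpfr_set(t, c3n, MPFR_RNDN);
    RAT_TERM(t, 105, 3, 6, 1);
    /* N-group */
    mpfr_set(t, N, MPFR_RNDN);
    RAT_TERM(t, 1050, 4, 5, 1);
    mpfr_mul_ui(t, N, 3, MPFR_RNDN);
    RAT_TERM(t, 2800, 5, 4, 1);
    mpfr_set(t, N, MPFR_RNDN);
    RAT_TERM(t, 800, 6, 3, 1);
    mpfr_set(t, N, MPFR_RNDN);
    RAT_TERM(t, 640, 7, 2, 1);
    mpfr_mul_ui(t, N, 3, MPFR_RNDN);
    RAT_TERM(t, 1280, 8, 1, 1);
    /* attractive part, subtracted: - y/(4 u s^2) - 3 y/(8 u^2 s) */
    mpfr_set_si(t, -1, MPFR_RNDN);
    RAT_TERM(t, 4, 1, 2, 0);
    mpfr_set_si(t, -3, MPFR_RNDN);
    RAT_TERM(t, 8, 2, 1, 0);

#undef RAT_TERM
    mpfr_clears(s, t, term, upow, spow, (mpfr_ptr) 0);
}

SEXP C_gdiff_mpfr(SEXP y0_, SEXP yL_, SEXP h_, SEXP a_, SEXP sigma_, SEXP prec_)
{
    const double y0d = Rf_asReal(y0_), yLd = Rf_asReal(yL_);
    const double hd = Rf_asReal(h_), ad = Rf_asReal(a_);
    const double sigd = Rf_asReal(sigma_);
    const mpfr_prec_t prec = (mpfr_prec_t) Rf_asInteger(prec_);

    if (prec < 64 || prec > 1 << 20)
        Rf_error("C_gdiff_mpfr: precision out of range");

    mpfr_t y0, yL, h, a, sig6, a2, h2, a4, a6, h4, h6;
    mpfr_t u, N, c2n, c3n, coefA, acc, t1, t2, t3;
    mpfr_inits2(prec, y0, yL, h, a, sig6, a2, h2, a4, a6, h4, h6,
                u, N, c2n, c3n, coefA, acc, t1, t2, t3, (mpfr_ptr) 0);

    mpfr_set_d(y0, y0d, MPFR_RNDN);
    mpfr_set_d(yL, yLd, MPFR_RNDN);
    mpfr_set_d(h, hd, MPFR_RNDN);
    mpfr_set_d(a, ad, MPFR_RNDN);
    mpfr_set_d(sig6, sigd, MPFR_RNDN);
    mpfr_pow_ui(sig6, sig6, 6, MPFR_RNDN);

    mpfr_sqr(a2, a, MPFR_RNDN);
    mpfr_sqr(h2, h, MPFR_RNDN);
    mpfr_sqr(a4, a2, MPFR_RNDN);
    mpfr_mul(a6, a4, a2, MPFR_RNDN);
    mpfr_sqr(h4, h2, MPFR_RNDN);
    mpfr_mul(h6, h4, h2, MPFR_RNDN);
    mpfr_sub(u, h2, a2, MPFR_RNDN);

    /* N = 16 a6 + 216 a4 h2 + 378 a2 h4 + 105 h6 */
    mpfr_mul_ui(N, a6, 16, MPFR_RNDN);
    mpfr_mul(t1, a4, h2, MPFR_RNDN);
    mpfr_mul_ui(t1, t1, 216, MPFR_RNDN);
    mpfr_add(N, N, t1, MPFR_RNDN);
    mpfr_mul(t1, a2, h4, MPFR_RNDN);
    mpfr_mul_ui(t1, t1, 378, MPFR_RNDN);
    mpfr_add(N, N, t1, MPFR_RNDN);
    mpfr_mul_ui(t1, h6, 105, MPFR_RNDN);
    mpfr_add(N, N, t1, MPFR_RNDN);

    /* c2n = 4 (4 a6 - 9 a4 h2) */
    mpfr_mul(t1, a4, h2, MPFR_RNDN);
    mpfr_mul_ui(t1, t1, 9, MPFR_RNDN);
    mpfr_mul_ui(c2n, a6, 4, MPFR_RNDN);
    mpfr_sub(c2n, c2n, t1, MPFR_RNDN);
    mpfr_mul_ui(c2n, c2n, 4, MPFR_RNDN);

    /* c3n = 11 a6 - 9 a4 h2 + 63 a2 h4 */
    mpfr_mul_ui(c3n, a6, 11, MPFR_RNDN);
    mpfr_mul(t1, a4, h2, MPFR_RNDN);
    mpfr_mul_ui(t1, t1, 9, MPFR_RNDN);
    mpfr_sub(c3n, c3n, t1, MPFR_RNDN);
    mpfr_mul(t1, a2, h4, MPFR_RNDN);
    mpfr_mul_ui(t1, t1, 63, MPFR_RNDN);
    mpfr_add(c3n, c3n, t1, MPFR_RNDN);

    mpfr_set_ui(acc, 0, MPFR_RNDN);
    acc_rational(acc, yL, u, a6, c2n, c3n, N, sig6, +1, prec);
    acc_rational(acc, y0, u, a6, c2n, c3n, N, sig6, -1, prec);

    /* coefA = sig6 * 3 N / (1280 u^8) - 3 / (8 u^2) */
    mpfr_pow_ui(t1, u, 8, MPFR_RNDN);
    mpfr_mul_ui(t1, t1, 1280, MPFR_RNDN);
    mpfr_mul(coefA, N, sig6, MPFR_RNDN);
    mpfr_mul_ui(coefA, coefA, 3, MPFR_RNDN);
    mpfr_div(coefA, coefA, t1, MPFR_RNDN);
    mpfr_sqr(t1, u, MPFR_RNDN);
    mpfr_mul_ui(t1, t1, 8, MPFR_RNDN);
    mpfr_ui_div(t1, 3, t1, MPFR_RNDN);
    mpfr_sub(coefA, coefA, t1, MPFR_RNDN);

    if (mpfr_sgn(u) > 0) {
        /* tail = coefA * (atan(yL/squ) - atan(y0/squ)) / squ */
        mpfr_sqrt(t1, u, MPFR_RNDN);        /* squ */
        mpfr_div(t2, yL, t1, MPFR_RNDN);
        mpfr_atan(t2, t2, MPFR_RNDN);
        mpfr_div(t3, y0, t1, MPFR_RNDN);
        mpfr_atan(t3, t3, MPFR_RNDN);
        mpfr_sub(t2, t2, t3, MPFR_RNDN);
        mpfr_div(t2, t2, t1, MPFR_RNDN);
        mpfr_mul(t2, t2, coefA, MPFR_RNDN);
        mpfr_add(acc, acc, t2, MPFR_RNDN);
    } else {
        /* v = sqrt(-u); tail = coefA * log1p(-2 v (yL-y0) /
         *                                    ((v+yL)(v-y0))) / (2 v)   */
        mpfr_neg(t1, u, MPFR_RNDN);
        mpfr_sqrt(t1, t1, MPFR_RNDN);       /* v */
        mpfr_add(t2, t1, yL, MPFR_RNDN);
        mpfr_sub(t3, t1, y0, MPFR_RNDN);
        mpfr_mul(t2, t2, t3, MPFR_RNDN);    /* den */
        mpfr_sub(t3, yL, y0, MPFR_RNDN);
        mpfr_mul(t3, t3, t1, MPFR_RNDN);
        mpfr_mul_si(t3, t3, -2, MPFR_RNDN);
        mpfr_div(t3, t3, t2, MPFR_RNDN);
        mpfr_log1p(t3, t3, MPFR_RNDN);
        mpfr_div(t3, t3, t1, MPFR_RNDN);
        mpfr_div_ui(t3, t3, 2, MPFR_RNDN);
        mpfr_mul(t3, t3, coefA, MPFR_RNDN);
        mpfr_add(acc, acc, t3, MPFR_RNDN);
    }

    const double out = mpfr_get_d(acc, MPFR_RNDN);
    mpfr_clears(y0, yL, h, a, sig6, a2, h2, a4, a6, h4, h6,
                u, N, c2n, c3n, coefA, acc, t1, t2, t3, (mpfr_ptr) 0);
    mpfr_free_cache();
    return Rf_ScalarReal(out);
}
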