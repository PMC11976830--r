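# MPFR/GMP live in the same prefix as R itself (R_HOME = <prefix>/lib/R).
RS_PREFIX = $(R_HOME)/../..
PKG_CPPFLAGS = -I"$(RS_PREFIX)/include"
PKG_LIBS = -L"$(RS_PREFIX)/lib" -Wl,-rpath,"$(RS_PREFIX)/lib" -lmpfr -lgmp
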