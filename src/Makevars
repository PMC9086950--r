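# bitset engine relies on hardware popcount; -mpopcnt (SSE4.2-era, 2008+)
PKG_CXXFLAGS = -O3 -mpopcnt -funroll-loops
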