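network unknown {
}
variable A {
  type discrete [ 2 ] { s0, s1 };
}
variable B {
  type discrete [ 3 ] { s0, s1, s2 };
}
variable C {
  type discrete [ 2 ] { s0, s1 };
}
probability ( A ) {
  table 0.69999999999999996, 0.29999999999999999;
}
probability ( B | A ) {
  (s0) 0.59999999999999998, 0.29999999999999999, 0.10000000000000001;
  (s1) 0.10000000000000001, 0.20000000000000001, 0.69999999999999996;
}
probability ( C | B ) {
  (s0) 0.90000000000000002, 0.10000000000000001;
  (s1) 0.5, 0.5;
  (s2) 0.20000000000000001, 0.80000000000000004;
}
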