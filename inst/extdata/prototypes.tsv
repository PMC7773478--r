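ramp_up	ramp_down	peak	valley	step
-5.000000000000	 5.000000000000	-5.000000000000	 5.000000000000	-5
-3.888888888889	 3.888888888889	-2.777777777778	 2.777777777778	-5
-2.777777777778	 2.777777777778	-0.555555555556	 0.555555555556	-5
-1.666666666667	 1.666666666667	 1.666666666667	-1.666666666667	-5
-0.555555555556	 0.555555555556	 3.888888888889	-3.888888888889	-5
 0.555555555556	-0.555555555556	 3.888888888889	-3.888888888889	 5
 1.666666666667	-1.666666666667	 1.666666666667	-1.666666666667	 5
 2.777777777778	-2.777777777778	-0.555555555556	 0.555555555556	 5
 3.888888888889	-3.888888888889	-2.777777777778	 2.777777777778	 5
 5.000000000000	-5.000000000000	-5.000000000000	 5.000000000000	 5
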