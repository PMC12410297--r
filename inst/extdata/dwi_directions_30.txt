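-0.64852344 -0.33722014 0.6824221
-0.47102031 0.84260838 0.26105742
0.81535719 0.57646726 0.05364839
0.79068831 0.01565078 0.61201884
-0.26912976 -0.31195077 0.91118378
0.16075756 -0.48402093 0.86016321
0.89908748 -0.33550677 0.28120615
0.4653299 -0.13185257 0.87526166
0.60645502 -0.50307659 0.61573229
0.04340977 0.0222033 0.9988106
-0.44130486 0.12952072 0.88796081
-0.98053396 0.1361242 0.1415039
-0.55714725 0.52160693 0.64615258
0.41136493 0.33859296 0.84624683
0.24205599 -0.96195525 0.12669252
0.31035493 0.73430821 0.60371456
-0.24620251 -0.71215032 0.65743916
0.65030452 -0.73231748 0.20202756
0.70733481 0.49176698 0.50778214
-0.6125541 -0.70614103 0.3551652
-0.06770197 0.45343698 0.88871331
-0.80431224 0.12113327 0.58172893
-0.21720419 -0.94501914 0.24446095
0.05074241 0.97054037 0.2355347
-0.81247447 0.53864157 0.2230482
-0.16181618 0.78045385 0.60391003
0.22494548 -0.80909185 0.54292716
0.96290194 0.16463971 0.21380743
0.48880978 0.85770518 0.15939519
-0.90590073 -0.29357318 0.30521903
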