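subject,location,window_s,accuracy_pct
Sub1,Left,5,82.4
Sub2,Left,5,87.2
Sub3,Left,5,80
Sub4,Left,5,84.1
Sub5,Left,5,94.1
Sub6,Left,5,91.4
Sub7,Left,5,90
Sub8,Left,5,78.3
Sub1,Mid,5,88.3
Sub2,Mid,5,95.5
Sub3,Mid,5,87.2
Sub4,Mid,5,76.9
Sub5,Mid,5,92.1
Sub6,Mid,5,97.9
Sub7,Mid,5,88.9
Sub8,Mid,5,84.1
Sub1,Right,5,84.5
Sub2,Right,5,80
Sub3,Right,5,72.1
Sub4,Right,5,85.2
Sub5,Right,5,93.1
Sub6,Right,5,87.6
Sub7,Right,5,87.9
Sub8,Right,5,77.2
Sub1,Left-Mid,5,89.3
Sub2,Left-Mid,5,98.3
Sub3,Left-Mid,5,87.2
Sub4,Left-Mid,5,83.8
Sub5,Left-Mid,5,96.9
Sub6,Left-Mid,5,96.2
Sub7,Left-Mid,5,92.4
Sub8,Left-Mid,5,90.7
Sub1,Right-Mid,5,89
Sub2,Right-Mid,5,97.6
Sub3,Right-Mid,5,90
Sub4,Right-Mid,5,85.2
Sub5,Right-Mid,5,99.3
Sub6,Right-Mid,5,96.9
Sub7,Right-Mid,5,93.4
Sub8,Right-Mid,5,88.3
Sub1,Whole,5,92.1
Sub2,Whole,5,98.6
Sub3,Whole,5,91.4
Sub4,Whole,5,89.3
Sub5,Whole,5,98.6
Sub6,Whole,5,98.3
Sub7,Whole,5,93.1
Sub8,Whole,5,90.3
Sub1,Left,10,82.9
Sub2,Left,10,88.6
Sub3,Left,10,79.3
Sub4,Left,10,89.3
Sub5,Left,10,94.3
Sub6,Left,10,91.4
Sub7,Left,10,90.7
Sub8,Left,10,84.3
Sub1,Mid,10,92.1
Sub2,Mid,10,94.3
Sub3,Mid,10,70.7
Sub4,Mid,10,75
Sub5,Mid,10,91.4
Sub6,Mid,10,97.9
Sub7,Mid,10,92.2
Sub8,Mid,10,87.1
Sub1,Right,10,85
Sub2,Right,10,90.7
Sub3,Right,10,72.1
Sub4,Right,10,80
Sub5,Right,10,96.4
Sub6,Right,10,85
Sub7,Right,10,82.2
Sub8,Right,10,80.7
Sub1,Left-Mid,10,91.4
Sub2,Left-Mid,10,98.6
Sub3,Left-Mid,10,86.4
Sub4,Left-Mid,10,86.4
Sub5,Left-Mid,10,97.1
Sub6,Left-Mid,10,97.1
Sub7,Left-Mid,10,93.6
Sub8,Left-Mid,10,87.9
Sub1,Right-Mid,10,89.3
Sub2,Right-Mid,10,93.6
Sub3,Right-Mid,10,89.3
Sub4,Right-Mid,10,90.7
Sub5,Right-Mid,10,99.3
Sub6,Right-Mid,10,97.9
Sub7,Right-Mid,10,94.4
Sub8,Right-Mid,10,90
Sub1,Whole,10,91.4
Sub2,Whole,10,99.3
Sub3,Whole,10,81.4
Sub4,Whole,10,85.7
Sub5,Whole,10,97.9
Sub6,Whole,10,98.6
Sub7,Whole,10,92.7
Sub8,Whole,10,91.4
Sub1,Left,20,86.7
Sub2,Left,20,93.3
Sub3,Left,20,83.3
Sub4,Left,20,93.3
Sub5,Left,20,98.3
Sub6,Left,20,96.7
Sub7,Left,20,86.6
Sub8,Left,20,88.3
Sub1,Mid,20,95
Sub2,Mid,20,100
Sub3,Mid,20,81.7
Sub4,Mid,20,70
Sub5,Mid,20,98.3
Sub6,Mid,20,100
Sub7,Mid,20,94.7
Sub8,Mid,20,93.3
Sub1,Right,20,83.3
Sub2,Right,20,93.3
Sub3,Right,20,70
Sub4,Right,20,86.7
Sub5,Right,20,93.3
Sub6,Right,20,90
Sub7,Right,20,85.2
Sub8,Right,20,90
Sub1,Left-Mid,20,88.3
Sub2,Left-Mid,20,98.3
Sub3,Left-Mid,20,86.7
Sub4,Left-Mid,20,91.7
Sub5,Left-Mid,20,98.3
Sub6,Left-Mid,20,96.7
Sub7,Left-Mid,20,95.2
Sub8,Left-Mid,20,93.3
Sub1,Right-Mid,20,90
Sub2,Right-Mid,20,95
Sub3,Right-Mid,20,85
Sub4,Right-Mid,20,93.3
Sub5,Right-Mid,20,100
Sub6,Right-Mid,20,96.7
Sub7,Right-Mid,20,94.7
Sub8,Right-Mid,20,88.3
Sub1,Whole,20,93.3
Sub2,Whole,20,95
Sub3,Whole,20,85
Sub4,Whole,20,90
Sub5,Whole,20,100
Sub6,Whole,20,93.3
Sub7,Whole,20,95.2
Sub8,Whole,20,93.3
Sub1,Left,25,100
Sub2,Left,25,96.7
Sub3,Left,25,90
Sub4,Left,25,93.3
Sub5,Left,25,100
Sub6,Left,25,86.7
Sub7,Left,25,96.7
Sub8,Left,25,93.3
Sub1,Mid,25,93.3
Sub2,Mid,25,100
Sub3,Mid,25,83.3
Sub4,Mid,25,86.7
Sub5,Mid,25,100
Sub6,Mid,25,100
Sub7,Mid,25,96.7
Sub8,Mid,25,90
Sub1,Right,25,83.3
Sub2,Right,25,96.7
Sub3,Right,25,76.7
Sub4,Right,25,90
Sub5,Right,25,100
Sub6,Right,25,93.3
Sub7,Right,25,96.7
Sub8,Right,25,90
Sub1,Left-Mid,25,96.7
Sub2,Left-Mid,25,100
Sub3,Left-Mid,25,83.3
Sub4,Left-Mid,25,93.3
Sub5,Left-Mid,25,100
Sub6,Left-Mid,25,100
Sub7,Left-Mid,25,97.5
Sub8,Left-Mid,25,96.7
Sub1,Right-Mid,25,100
Sub2,Right-Mid,25,100
Sub3,Right-Mid,25,80
Sub4,Right-Mid,25,93.3
Sub5,Right-Mid,25,100
Sub6,Right-Mid,25,100
Sub7,Right-Mid,25,96.7
Sub8,Right-Mid,25,93.3
Sub1,Whole,25,100
Sub2,Whole,25,100
Sub3,Whole,25,83.3
Sub4,Whole,25,90
Sub5,Whole,25,96.7
Sub6,Whole,25,100
Sub7,Whole,25,93.3
Sub8,Whole,25,90
Sub1,Left,48,100
Sub2,Left,48,95
Sub3,Left,48,85
Sub4,Left,48,100
Sub5,Left,48,100
Sub6,Left,48,85
Sub7,Left,48,95
Sub8,Left,48,100
Sub1,Mid,48,100
Sub2,Mid,48,100
Sub3,Mid,48,90
Sub4,Mid,48,90
Sub5,Mid,48,100
Sub6,Mid,48,100
Sub7,Mid,48,90
Sub8,Mid,48,95
Sub1,Right,48,90
Sub2,Right,48,95
Sub3,Right,48,90
Sub4,Right,48,95
Sub5,Right,48,100
Sub6,Right,48,95
Sub7,Right,48,100
Sub8,Right,48,95
Sub1,Left-Mid,48,100
Sub2,Left-Mid,48,100
Sub3,Left-Mid,48,95
Sub4,Left-Mid,48,100
Sub5,Left-Mid,48,100
Sub6,Left-Mid,48,100
Sub7,Left-Mid,48,96.7
Sub8,Left-Mid,48,95
Sub1,Right-Mid,48,100
Sub2,Right-Mid,48,100
Sub3,Right-Mid,48,90
Sub4,Right-Mid,48,95
Sub5,Right-Mid,48,100
Sub6,Right-Mid,48,100
Sub7,Right-Mid,48,95
Sub8,Right-Mid,48,100
Sub1,Whole,48,100
Sub2,Whole,48,100
Sub3,Whole,48,90
Sub4,Whole,48,100
Sub5,Whole,48,100
Sub6,Whole,48,100
Sub7,Whole,48,95
Sub8,Whole,48,100
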