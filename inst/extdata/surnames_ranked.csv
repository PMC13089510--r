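name,rank
Smith,1
Johnson,2
Williams,3
Brown,4
Jones,5
Garcia,6
Miller,7
Davis,8
Rodriguez,9
Martinez,10
Hernandez,11
Lopez,12
Gonzalez,13
Wilson,14
Anderson,15
Thomas,16
Taylor,17
Moore,18
Jackson,19
Martin,20
Lee,21
Perez,22
Thompson,23
White,24
Harris,25
Sanchez,26
Clark,27
Ramirez,28
Lewis,29
Robinson,30
Walker,31
Young,32
Allen,33
King,34
Wright,35
Scott,36
Torres,37
Nguyen,38
Hill,39
Flores,40
Green,41
Adams,42
Nelson,43
Baker,44
Hall,45
Rivera,46
Campbell,47
Mitchell,48
Carter,49
Roberts,50
Gomez,51
Phillips,52
Evans,53
Turner,54
Diaz,55
Parker,56
Cruz,57
Edwards,58
Collins,59
Reyes,60
Stewart,61
Morris,62
Morales,63
Murphy,64
Cook,65
Rogers,66
Gutierrez,67
Ortiz,68
Morgan,69
Cooper,70
Peterson,71
Bailey,72
Reed,73
Kelly,74
Howard,75
Ramos,76
Kim,77
Cox,78
Ward,79
Richardson,80
Watson,81
Brooks,82
Chavez,83
Wood,84
James,85
Bennett,86
Gray,87
Mendoza,88
Ruiz,89
Hughes,90
Price,91
Alvarez,92
Castillo,93
Sanders,94
Patel,95
Myers,96
Long,97
Ross,98
Foster,99
Jimenez,100
Powell,101
Jenkins,102
Perry,103
Russell,104
Sullivan,105
Bell,106
Coleman,107
Butler,108
Henderson,109
Barnes,110
Gonzales,111
Fisher,112
Vasquez,113
Simmons,114
Romero,115
Jordan,116
Patterson,117
Alexander,118
Hamilton,119
Graham,120
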